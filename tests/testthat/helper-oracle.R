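# exhaustive O(n^2) minimum cross-distance oracle, independent of the
# package's grid search: scans every pair, accumulating squared
# coordinate differences in x,y,z order
brute_min_cross <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    dx <- B[, 1] - A[i, 1]
    dy <- B[, 2] - A[i, 2]
    dz <- B[, 3] - A[i, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    m <- min(d2)
    if (m < best) best <- m
  }
  sqrt(best)
}

# build an in-memory chain model from a coordinate matrix
chain_from_coords <- function(coords, id = "A", copy = 1L,
                              residue_name = "ALA", atom_used = "CB") {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  list(chain_id = id, copy_index = copy,
       points = data.frame(seq_index = seq_len(n),
                           residue_name = rep(residue_name, length.out = n),
                           x = coords[, 1], y = coords[, 2], z = coords[, 3],
                           atom_used = rep(atom_used, length.out = n),
                           stringsAsFactors = FALSE),
       n_skipped = 0L)
}

# random cloud of n points in a box of the given side
random_cloud <- function(n, side = 40, center = c(0, 0, 0)) {
  sweep(matrix(runif(3 * n, -side / 2, side / 2), ncol = 3), 2, center, "+")
}

# random proper rotation matrix (QR of a Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# atom-row frame for select_representative_atom tests
residue_rows <- function(resid, elety, x, y, z, alt = NA_character_, o = 1,
                         resno = 1L) {
  data.frame(resid = resid, elety = elety, x = x, y = y, z = z,
             alt = alt, o = o, resno = resno, stringsAsFactors = FALSE)
}

# synthetic pair frame of n distinct canonical pairs
synth_pairs <- function(n, prefix = "P") {
  data.frame(first = sprintf("%sA%06d", prefix, seq_len(n)),
             second = sprintf("%sB%06d", prefix, seq_len(n)),
             stringsAsFactors = FALSE)
}
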