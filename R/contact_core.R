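#' Contact-rule configuration
#'
#' The non-interaction rule: a chain pair is non-interacting when the
#' minimum representative-atom distance between the chains is strictly
#' greater than the threshold. The default is the 8 Angstrom cutoff on
#' C-beta--C-beta (C-alpha for glycine) distances; a pair at exactly the
#' threshold counts as interacting, the conservative reading for a
#' negative dataset.
#'
#' @param threshold distance in Angstrom, must be positive.
#' @return list of class `contact_config`.
#' @export
contact_config <- function(threshold = 8.0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive distance in Angstrom")
  structure(list(threshold = threshold, comparison = "strict-greater"),
            class = "contact_config")
}

.chain_coords <- function(chain) {
  as.matrix(chain$points[, c("x", "y", "z"), drop = FALSE])
}

#' Minimum inter-chain representative-atom distance
#'
#' The minimum over all cross-chain pairs of points of the Euclidean
#' distance, computed with a compiled uniform-grid search that is exactly
#' equal to the exhaustive pairwise minimum.
#'
#' @param a,b chain models (elements of a `biounit`'s `chains` list), each
#'   with a `points` data.frame carrying `x`, `y`, `z`.
#' @return distance in Angstrom.
#' @export
min_interchain_distance <- function(a, b) {
  pa <- .chain_coords(a); pb <- .chain_coords(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stop("both chains must have at least one representative point")
  cpp_min_cross_distance(pa, pb)
}

#' Classify one chain pair under the strict distance rule
#'
#' @param a,b chain models.
#' @param cfg a [contact_config()].
#' @return one-row data.frame: `chain_a`, `copy_a`, `chain_b`, `copy_b`,
#'   `min_distance`, `non_interacting`.
#' @export
classify_chain_pair <- function(a, b, cfg = contact_config()) {
  d <- min_interchain_distance(a, b)
  data.frame(chain_a = a$chain_id, copy_a = a$copy_index,
             chain_b = b$chain_id, copy_b = b$copy_index,
             min_distance = d,
             non_interacting = d > cfg$threshold,
             stringsAsFactors = FALSE)
}

#' Classify every chain pair of a biological unit
#'
#' Enumerates each unordered pair of chain copies exactly once.
#'
#' @param unit a `biounit` from [read_biounit()].
#' @param cfg a [contact_config()].
#' @return data.frame with one row per pair (empty for single-chain
#'   units), plus columns `structure_id` and `assembly_id`.
#' @export
enumerate_chain_pairs <- function(unit, cfg = contact_config()) {
  ch <- unit$chains
  n <- length(ch)
  empty <- data.frame(structure_id = character(), assembly_id = character(),
                      chain_a = character(), copy_a = integer(),
                      chain_b = character(), copy_b = integer(),
                      min_distance = numeric(), non_interacting = logical(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k + 1L
    rows[[k]] <- classify_chain_pair(ch[[i]], ch[[j]], cfg)
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(structure_id = unit$structure_id,
                   assembly_id = unit$assembly_id,
                   stringsAsFactors = FALSE),
        out)
}
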