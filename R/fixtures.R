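# run expr with a private RNG stream; the caller's .Random.seed is restored
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","HIS","ILE","LEU",
          "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

.unit_vec <- function(v) v / sqrt(sum(v^2))

# compact random coil: CA trace with 3.8 A steps and mild direction
# persistence, pseudo-CB at 1.53 A from CA along a local frame normal
.random_coil <- function(n, gly_fraction = 0.1) {
  ca <- matrix(0, n, 3)
  dir <- .unit_vec(rnorm(3))
  for (i in 2:max(n, 2)) {
    if (i > n) break
    repeat {
      cand <- .unit_vec(dir + 0.8 * rnorm(3))
      p <- ca[i - 1, ] + 3.8 * cand
      # self-avoiding-ish: keep 3 A clearance from earlier residues
      if (i < 4 || min(sqrt(rowSums(sweep(ca[1:(i - 2), , drop = FALSE],
                                          2, p)^2))) > 3.0) break
    }
    dir <- cand
    ca[i, ] <- p
  }
  resname <- ifelse(runif(n) < gly_fraction, "GLY", sample(.aa3, n, TRUE))
  cb <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (resname[i] == "GLY") next
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] + c(1, 0, 0)
    nxt <- if (i < n) ca[i + 1, ] else ca[i, ] + c(0, 1, 0)
    u <- .unit_vec(ca[i, ] - prev + ca[i, ] - nxt + rnorm(3, sd = 1e-3))
    cb[i, ] <- ca[i, ] + 1.53 * u
  }
  list(ca = ca, cb = cb, resname = resname)
}

# representative-atom coordinates of a generated coil (CB, CA for GLY)
.coil_rep <- function(coil) {
  rep_xyz <- coil$cb
  isg <- coil$resname == "GLY" | is.na(rep_xyz[, 1])
  rep_xyz[isg, ] <- coil$ca[isg, ]
  rep_xyz
}

.min_cross <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

# place chains by rigid translation so every pair's minimum
# representative-atom distance hits its target gap (within tol).
# Initial layout from classical MDS on approximate centroid distances,
# then iterative closest-point relaxation; a few seeded restarts before
# declaring the target system infeasible.
.relax_offsets <- function(reps, gaps, tol = 0.05, max_iter = 2000,
                           restarts = 6, clearance = 25) {
  n <- length(reps)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cent <- lapply(reps, colMeans)
  radius <- vapply(seq_len(n), function(i)
    mean(sqrt(rowSums(sweep(reps[[i]], 2, cent[[i]])^2))), 0)

  init_mds <- function(jitter = 0) {
    D <- matrix(0, n, n)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      g <- if (is.na(gaps[i, j])) clearance else gaps[i, j]
      D[i, j] <- D[j, i] <- g + radius[i] + radius[j]
    }
    pos <- if (n == 2) rbind(c(0, 0, 0), c(D[1, 2], 0, 0)) else {
      mds <- stats::cmdscale(stats::as.dist(D), k = min(3, n - 1))
      mds <- matrix(as.numeric(mds), nrow = n)
      if (ncol(mds) < 3) cbind(mds, matrix(0, n, 3 - ncol(mds))) else mds[, 1:3]
    }
    lapply(seq_len(n), function(i)
      pos[i, ] - cent[[i]] + jitter * rnorm(3))
  }

  attempt <- function(off) {
    for (it in seq_len(max_iter)) {
      worst <- 0
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        g <- gaps[i, j]
        a <- sweep(reps[[i]], 2, off[[i]], "+")
        b <- sweep(reps[[j]], 2, off[[j]], "+")
        d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
        idx <- arrayInd(which.min(d2), dim(d2))
        m <- sqrt(max(d2[idx], 0))
        # unspecified pairs only need clearance: push apart, never pull
        err <- if (is.na(g)) min(m - clearance, 0) else m - g
        worst <- max(worst, abs(err))
        if (abs(err) < 0.5 * tol) next
        u <- if (m > 1e-9) .unit_vec(b[idx[2], ] - a[idx[1], ]) else
          .unit_vec(rnorm(3))
        step <- 0.45 * err
        off[[i]] <- off[[i]] + step * u
        off[[j]] <- off[[j]] - step * u
      }
      if (worst < tol) return(off)
    }
    NULL
  }

  for (r in seq_len(restarts)) {
    off <- attempt(init_mds(jitter = if (r == 1) 0 else 4 * r))
    if (!is.null(off)) return(off)
  }
  stop("infeasible fixture spec: pairwise gap targets did not converge")
}

#' Specification of a synthetic biological unit
#'
#' @param structure_id short structure identifier (PDB-id-like).
#' @param n_chains number of chains (named A, B, C, ...).
#' @param residues_per_chain residues in each chain.
#' @param gaps named numeric vector of target minimum representative-atom
#'   gaps in Angstrom between chain pairs, names like `"A-B"`; pairs left
#'   unnamed default to 25.
#' @param seed integer seed; fixed seed means byte-identical output files.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(structure_id = "s001", n_chains = 2,
                         residues_per_chain = 30, gaps = c("A-B" = 12),
                         seed = 1) {
  stopifnot(n_chains >= 1, n_chains <= 26, residues_per_chain >= 2)
  if (length(gaps) && any(gaps <= 0)) stop("gaps must be positive")
  structure(list(structure_id = structure_id, n_chains = n_chains,
                 residues_per_chain = residues_per_chain,
                 gaps = gaps, seed = seed), class = "fixture_spec")
}

.write_pdb_fixture <- function(chains, path) {
  lines <- character()
  serial <- 0L
  for (ch in chains) {
    n <- nrow(ch$ca)
    for (i in seq_len(n)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, ch$resname[i], ch$id, i,
        ch$ca[i, 1], ch$ca[i, 2], ch$ca[i, 3], 1, 0))
      if (!is.na(ch$cb[i, 1]) && ch$resname[i] != "GLY") {
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d  CB  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, ch$resname[i], ch$id, i,
          ch$cb[i, 1], ch$cb[i, 2], ch$cb[i, 3], 1, 0))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
}

.write_cif_fixture <- function(chains, structure_id, path) {
  hdr <- c(paste0("data_", toupper(structure_id)), "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- character()
  serial <- 0L
  for (ei in seq_along(chains)) {
    ch <- chains[[ei]]
    for (i in seq_len(nrow(ch$ca))) {
      emit <- function(atom, xyz) {
        serial <<- serial + 1L
        sprintf("ATOM %d C %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
                serial, atom, ch$resname[i], ch$id, ei, i,
                xyz[1], xyz[2], xyz[3], i, ch$resname[i], ch$id, atom)
      }
      rows <- c(rows, emit("CA", ch$ca[i, ]))
      if (!is.na(ch$cb[i, 1]) && ch$resname[i] != "GLY")
        rows <- c(rows, emit("CB", ch$cb[i, ]))
    }
  }
  writeLines(c(hdr, rows, "#"), path)
}

#' Generate a synthetic biological unit with controlled chain gaps
#'
#' Chains are built as compact random coils (3.8 Angstrom C-alpha spacing,
#' pseudo-C-beta at standard bond length) and rigidly translated until
#' each requested pair's exhaustively computed minimum representative-atom
#' distance matches its target gap to within 0.1 Angstrom. The unit is
#' written both as PDB and as single-block mmCIF, together with a
#' machine-readable ground-truth table of the realized gaps and the
#' non-interaction classification they imply under a given threshold.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param threshold threshold in Angstrom used for the ground-truth labels.
#' @return list: `pdb`, `cif`, `truth` (file paths), `truth_table`
#'   (data.frame `chain_a`, `chain_b`, `gap`, `non_interacting`),
#'   `chains` (generated coordinates).
#' @export
make_biounit <- function(spec, dir, threshold = 8.0) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$seed, {
    ids <- LETTERS[seq_len(spec$n_chains)]
    coils <- lapply(ids, function(i) .random_coil(spec$residues_per_chain))
    reps <- lapply(coils, .coil_rep)
    gaps <- matrix(NA_real_, spec$n_chains, spec$n_chains)
    if (spec$n_chains > 1) {
      for (i in 1:(spec$n_chains - 1)) for (j in (i + 1):spec$n_chains) {
        nm <- paste(ids[i], ids[j], sep = "-")
        if (nm %in% names(spec$gaps)) gaps[i, j] <- spec$gaps[[nm]]
      }
      off <- .relax_offsets(reps, gaps)
    } else off <- list(c(0, 0, 0))
    chains <- lapply(seq_along(coils), function(k) {
      co <- coils[[k]]
      co$ca <- sweep(co$ca, 2, off[[k]], "+")
      ok <- !is.na(co$cb[, 1])
      co$cb[ok, ] <- sweep(co$cb[ok, , drop = FALSE], 2, off[[k]], "+")
      co$id <- ids[k]
      co
    })
    pdb_path <- file.path(dir, paste0(spec$structure_id, ".pdb"))
    cif_path <- file.path(dir, paste0(spec$structure_id, ".cif"))
    .write_pdb_fixture(chains, pdb_path)
    .write_cif_fixture(chains, spec$structure_id, cif_path)
    truth <- NULL
    if (spec$n_chains > 1) {
      reps2 <- lapply(chains, .coil_rep)
      rows <- list()
      for (i in 1:(spec$n_chains - 1)) for (j in (i + 1):spec$n_chains) {
        # realized gap re-measured exhaustively at file precision (3 dp)
        g <- .min_cross(round(reps2[[i]], 3), round(reps2[[j]], 3))
        rows[[length(rows) + 1L]] <-
          data.frame(chain_a = ids[i], chain_b = ids[j], gap = g,
                     non_interacting = g > threshold,
                     stringsAsFactors = FALSE)
      }
      truth <- do.call(rbind, rows)
    } else {
      truth <- data.frame(chain_a = character(), chain_b = character(),
                          gap = numeric(), non_interacting = logical())
    }
    truth_path <- file.path(dir, paste0(spec$structure_id, ".truth.tsv"))
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(pdb = pdb_path, cif = cif_path, truth = truth_path,
         truth_table = truth, chains = chains)
  })
}

#' Generate a synthetic MITAB file of known interactions
#'
#' Writes a PSI-MI TAB 2.5 file whose uniprotkb pairs hit exactly
#' `round(hit_fraction * n)` of the candidate pairs; some hits are written
#' in swapped orientation and a few non-uniprotkb (small-molecule) rows
#' are included to exercise lenient parsing. Ground truth (the hit keys
#' and the expected survivor count after subtraction) is returned.
#'
#' @param pairs candidate pair data.frame (columns `first`, `second`).
#' @param hit_fraction fraction of candidates to mark as interacting.
#' @param seed integer seed.
#' @param path output MITAB path.
#' @param n_extra number of distractor interactions not in the candidate
#'   set.
#' @return list: `path`, `hits` (canonical keys), `n_hits`,
#'   `expected_survivors`.
#' @export
make_known_interactions <- function(pairs, hit_fraction, seed, path,
                                    n_extra = 5) {
  stopifnot(hit_fraction >= 0, hit_fraction <= 1)
  cp <- dedup_pairs(canonical_pairs(pairs$first, pairs$second))
  n <- nrow(cp)
  k <- round(hit_fraction * n)
  .with_seed(seed, {
    hit_idx <- if (k > 0) sample.int(n, k) else integer()
    a <- cp$first[hit_idx]; b <- cp$second[hit_idx]
    swap <- runif(length(a)) < 0.5
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    extra_a <- sprintf("X%05d", sample.int(99999, n_extra))
    extra_b <- sprintf("Y%05d", sample.int(99999, n_extra))
    rows <- c(
      paste0("uniprotkb:", c(a, extra_a), "\t", "uniprotkb:", c(b, extra_b)),
      "chebi:CHEBI:15377\tuniprotkb:P99999",
      "uniprotkb:P99998\tchebi:CHEBI:16236")
    rows <- sample(rows)  # shuffle row order
    pad <- paste(rep("-", 13), collapse = "\t")
    writeLines(paste(rows, pad, sep = "\t"), path)
  })
  list(path = path, hits = pair_keys(cp[sort(hit_idx), , drop = FALSE]),
       n_hits = k, expected_survivors = n - k)
}

#' Generate a synthetic PAS corpus
#'
#' JSON-lines records with controlled argument/sentence lengths; exactly
#' `round(n * negated_fraction)` records carry both a lexicon verb and a
#' negation token (so must pass the candidate filter), the rest fail it by
#' lacking a negation, using an out-of-lexicon verb, or both.
#'
#' @param n number of records.
#' @param negated_fraction fraction that must pass
#'   [is_negated_interaction()].
#' @param seed integer seed.
#' @param path output JSON-lines path.
#' @param cfg [score_config()] supplying the lexicon to draw verbs from.
#' @return data.frame of the records plus a logical `label` column (TRUE
#'   where the record must pass the filter).
#' @export
make_pas_corpus <- function(n, negated_fraction, seed, path,
                            cfg = score_config()) {
  stopifnot(n >= 0, negated_fraction >= 0, negated_fraction <= 1)
  k <- round(n * negated_fraction)
  .with_seed(seed, {
    if (n == 0) {
      writeLines(character(), path)
      return(invisible(data.frame()))
    }
    lex <- names(cfg$verb_lexicon)
    out_verbs <- c("phosphorylate", "activate", "inhibit", "regulate",
                   "express", "cleave")
    prot <- function(m) sprintf("PROT%03d", sample.int(400, m, TRUE))
    label <- c(rep(TRUE, k), rep(FALSE, n - k))
    relation <- ifelse(label, sample(lex, n, TRUE),
                       NA)  # filled below for negatives
    negation <- ifelse(label,
                       sample(c(cfg$common_negations[1:4], "scarcely"),
                              n, TRUE, prob = c(rep(0.22, 4), 0.12)),
                       NA)
    for (i in which(!label)) {
      mode <- sample(3, 1)
      relation[i] <- if (mode == 1) sample(out_verbs, 1) else
        if (mode == 2) sample(lex, 1) else sample(out_verbs, 1)
      negation[i] <- if (mode == 1) sample(cfg$common_negations, 1) else NA
    }
    agent <- prot(n); theme <- prot(n)
    same <- runif(n) < 0.1
    theme[same] <- agent[same]
    agent_len <- sample(1:15, n, TRUE)
    theme_len <- sample(1:15, n, TRUE)
    sentence_len <- sample(5:60, n, TRUE)
    sentence <- vapply(sentence_len, function(L)
      paste(rep("w", L), collapse = " "), "")
    df <- data.frame(agent = agent, theme = theme, relation = relation,
                     negation = negation, sentence = sentence,
                     agent_len = agent_len, theme_len = theme_len,
                     sentence_len = sentence_len, label = label,
                     stringsAsFactors = FALSE)
    df <- df[sample.int(n), , drop = FALSE]
    rownames(df) <- NULL
    lines <- vapply(seq_len(n), function(i) {
      rec <- as.list(df[i, setdiff(names(df), "label")])
      if (is.na(rec$negation)) rec$negation <- NULL
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, "")
    writeLines(lines, path)
    df
  })
}

#' Generate chain-to-protein and protein-to-domain mapping tables
#'
#' Helpers completing a fully synthetic pipeline run: every chain of every
#' structure gets a deterministic accession, and every accession gets a
#' small set of Pfam domains.
#'
#' @param structure_ids character vector of structure ids.
#' @param chain_ids list (parallel to `structure_ids`) of chain id
#'   vectors.
#' @param path output TSV.
#' @param accessions accession vector (recycled over chains in order); by
#'   default `P00001`, `P00002`, ...
#' @return the mapping data.frame (invisibly the file is written).
#' @export
make_chain_mapping_table <- function(structure_ids, chain_ids, path,
                                     accessions = NULL) {
  sid <- rep(structure_ids, lengths(chain_ids))
  cid <- unlist(chain_ids)
  if (is.null(accessions))
    accessions <- sprintf("P%05d", seq_along(cid))
  df <- data.frame(structure_id = sid, chain_id = cid,
                   accession = accessions, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

#' @rdname make_chain_mapping_table
#' @param domains_per_protein how many Pfam domains each accession gets.
#' @param seed integer seed for domain assignment.
#' @export
make_domain_mapping_table <- function(accessions, domains_per_protein = 2,
                                      seed = 1, path) {
  .with_seed(seed, {
    accessions <- unique(accessions)
    rows <- lapply(accessions, function(a)
      data.frame(accession = a,
                 pfam = sprintf("PF%05d", sample.int(300, domains_per_protein)),
                 stringsAsFactors = FALSE))
    df <- do.call(rbind, rows)
    df <- df[!duplicated(df), , drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    df
  })
}
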