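#' Load a chain-to-protein mapping table
#'
#' SIFTS-style TSV with header columns `structure_id`, `chain_id`,
#' `accession`: one protein accession per structure chain. Duplicate keys
#' are tolerated only when they agree.
#'
#' @param path TSV file.
#' @return data.frame of class `chain_mapping` with the three columns.
#' @export
load_chain_mapping <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("structure_id", "chain_id", "accession")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("chain mapping ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!nzchar(df$accession)))
    stop("chain mapping has empty accession(s)")
  key <- paste(df$structure_id, df$chain_id, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    agree <- tapply(df$accession, key, function(a) length(unique(a)) == 1L)
    if (!all(agree))
      stop("conflicting chain mapping for key(s): ",
           paste(names(agree)[!agree], collapse = ", "))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("chain_mapping", "data.frame")
  df
}

#' Load a protein-to-Pfam domain mapping
#'
#' TSV with header columns `accession`, `pfam`; repeated rows per protein
#' list its domains. Pfam accessions must match `PF` + 5 digits.
#'
#' @param path TSV file.
#' @return named list: accession -> character vector of Pfam accessions
#'   (duplicates removed, order of first appearance).
#' @export
load_domain_mapping <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("accession", "pfam")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("domain mapping ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- !grepl("^PF[0-9]{5}$", df$pfam)
  if (any(bad))
    stop("malformed Pfam accession(s): ", paste(unique(df$pfam[bad]), collapse = ", "))
  lapply(split(df$pfam, df$accession), unique)
}

#' Consolidate chain-pair results into protein-level NIP records
#'
#' Maps chains to protein accessions and applies the consolidation rules:
#' within one assembly a protein pair is non-interacting only if ALL chain
#' copy pairs realizing it are beyond the threshold (one observed contact
#' falsifies non-interaction); across assemblies any observed contact
#' anywhere suppresses the pair globally. Self pairs (same accession on
#' both sides) are excluded. Chains absent from the mapping are dropped
#' with a message.
#'
#' @param results data.frame as returned by [enumerate_chain_pairs()]
#'   (rows from several units may be row-bound).
#' @param mapping a [load_chain_mapping()] table.
#' @param cfg a [contact_config()]; its threshold re-derives the
#'   non-interacting flag from `min_distance`.
#' @param collapse_isoforms drop isoform suffixes (`P12345-2` -> `P12345`)
#'   before pairing.
#' @return NIP records: data.frame with columns `first`, `second`,
#'   `source` (`"structure"`), `evidence`
#'   (semicolon-joined `structure:assembly:min_distance`), `method` (`""`),
#'   sorted by canonical pair.
#' @export
consolidate_protein_pairs <- function(results, mapping,
                                      cfg = contact_config(),
                                      collapse_isoforms = FALSE) {
  empty <- data.frame(first = character(), second = character(),
                      source = character(), evidence = character(),
                      method = character(), stringsAsFactors = FALSE)
  if (nrow(results) == 0L) return(empty)
  mkey <- paste(mapping$structure_id, mapping$chain_id, sep = "|")
  acc_a <- mapping$accession[match(paste(results$structure_id, results$chain_a,
                                         sep = "|"), mkey)]
  acc_b <- mapping$accession[match(paste(results$structure_id, results$chain_b,
                                         sep = "|"), mkey)]
  unmapped <- is.na(acc_a) | is.na(acc_b)
  if (any(unmapped))
    message(sum(unmapped), " chain pair(s) dropped: chain(s) not in mapping")
  results <- results[!unmapped, , drop = FALSE]
  acc_a <- acc_a[!unmapped]; acc_b <- acc_b[!unmapped]
  if (collapse_isoforms) {
    acc_a <- sub("-.*$", "", acc_a)
    acc_b <- sub("-.*$", "", acc_b)
  }
  selfpair <- acc_a == acc_b
  results <- results[!selfpair, , drop = FALSE]
  acc_a <- acc_a[!selfpair]; acc_b <- acc_b[!selfpair]
  if (nrow(results) == 0L) return(empty)

  cp <- canonical_pairs(acc_a, acc_b)
  unit <- paste(results$structure_id, results$assembly_id, sep = ":")
  grp <- paste(unit, pair_keys(cp), sep = "@")
  # per (unit, pair): minimum over all chain-copy realizations
  agg <- data.frame(grp = grp, unit = unit,
                    structure_id = results$structure_id,
                    assembly_id = results$assembly_id,
                    first = cp$first, second = cp$second,
                    d = results$min_distance, stringsAsFactors = FALSE)
  first_row <- !duplicated(agg$grp)
  unit_min <- tapply(agg$d, agg$grp, min)
  per_unit <- agg[first_row, c("grp", "structure_id", "assembly_id",
                               "first", "second"), drop = FALSE]
  per_unit$min_distance <- as.numeric(unit_min[per_unit$grp])
  per_unit$noninter <- per_unit$min_distance > cfg$threshold

  # cross-unit suppression: any contact anywhere removes the pair
  pk <- pair_keys(per_unit)
  ok_pair <- tapply(per_unit$noninter, pk, all)
  keep <- per_unit[ok_pair[pk], , drop = FALSE]
  if (nrow(keep) == 0L) return(empty)
  ev <- tapply(seq_len(nrow(keep)), pair_keys(keep), function(ii) {
    ii <- ii[order(keep$structure_id[ii], keep$assembly_id[ii],
                   method = "radix")]
    paste(sprintf("%s:%s:%.3f", keep$structure_id[ii], keep$assembly_id[ii],
                  keep$min_distance[ii]), collapse = ";")
  })
  uniq <- keep[!duplicated(pair_keys(keep)), c("first", "second"), drop = FALSE]
  out <- data.frame(first = uniq$first, second = uniq$second,
                    source = "structure",
                    evidence = as.character(ev[pair_keys(uniq)]),
                    method = "", stringsAsFactors = FALSE)
  out <- out[order(out$first, out$second, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand protein pairs into all Pfam domain pair combinations
#'
#' For a protein pair (A, B) with domains A1, A2, ... and B1, B2, ... the
#' full cross product A1-B1, A1-B2, A2-B1, ... is generated, canonicalized
#' and de-duplicated across all input pairs. Proteins with no mapped
#' domains contribute nothing. Domain self-pairs (D, D) are retained so
#' that homodomain interactions can later be subtracted.
#'
#' @param pairs data.frame with columns `first`, `second` (protein
#'   accessions).
#' @param domains a [load_domain_mapping()] list.
#' @return canonical Pfam pair data.frame; attribute `n_before_dedup` is
#'   the total cross-product cardinality sum(|dom(A)|*|dom(B)|).
#' @export
expand_domain_pairs <- function(pairs, domains) {
  out_a <- character(); out_b <- character()
  total <- 0L
  for (i in seq_len(nrow(pairs))) {
    da <- domains[[pairs$first[i]]]
    db <- domains[[pairs$second[i]]]
    if (is.null(da) || is.null(db) || length(da) == 0L || length(db) == 0L)
      next
    total <- total + length(da) * length(db)
    g <- expand.grid(a = da, b = db, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    out_a <- c(out_a, g$a); out_b <- c(out_b, g$b)
  }
  cp <- dedup_pairs(canonical_pairs(out_a, out_b))
  cp <- cp[order(cp$first, cp$second, method = "radix"), , drop = FALSE]
  rownames(cp) <- NULL
  attr(cp, "n_before_dedup") <- total
  cp
}
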