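#' Canonicalize unordered identifier pairs
#'
#' An unordered pair of accessions (protein or Pfam) is stored with its
#' members in a deterministic order so that equality between pairs ignores
#' orientation. Ordering is plain byte-wise (C collation) lexicographic
#' order, independent of the session locale.
#'
#' @param first,second character vectors of equal length; identifiers such
#'   as UniProt accessions (`P12345`) or Pfam accessions (`PF00001`).
#' @return A data.frame with columns `first` and `second` where
#'   `first <= second` row-wise.
#' @examples
#' canonical_pairs(c("Q1", "A2"), c("B9", "Z0"))
#' @export
canonical_pairs <- function(first, second) {
  first <- as.character(first)
  second <- as.character(second)
  stopifnot(length(first) == length(second))
  if (length(first) == 0L) {
    return(data.frame(first = character(), second = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(is.na(first) | is.na(second) | first == "" | second == ""))
    stop("pair members must be non-empty and non-NA")
  u <- sort(unique(c(first, second)), method = "radix")
  swap <- match(first, u) > match(second, u)
  data.frame(first = ifelse(swap, second, first),
             second = ifelse(swap, first, second),
             stringsAsFactors = FALSE)
}

#' @rdname canonical_pairs
#' @param pairs a data.frame with columns `first`, `second`.
#' @return `pair_keys()`: a character vector, one key per row, usable for
#'   set operations.
#' @export
pair_keys <- function(pairs) {
  paste(pairs$first, pairs$second, sep = "\t")
}

# de-duplicate a canonical pair frame, preserving first occurrence order
dedup_pairs <- function(pairs, quiet = TRUE) {
  dup <- duplicated(pair_keys(pairs))
  if (any(dup) && !quiet)
    message(sum(dup), " duplicate pair(s) removed")
  pairs[!dup, , drop = FALSE]
}

#' Construct an interaction set
#'
#' A set of canonical pairs with provenance, used as the subtrahend when
#' deriving stringent datasets (e.g. pairs reported as interacting in a
#' PSI-MI TAB export, or known interacting domain pairs from catalogues of
#' domain contacts in solved structures).
#'
#' @param pairs data.frame with columns `first`, `second` (canonicalized
#'   and de-duplicated on construction).
#' @param provenance free-text source description (file + dialect).
#' @return An object of class `interaction_set`.
#' @export
interaction_set <- function(pairs, provenance = "unspecified") {
  pairs <- dedup_pairs(canonical_pairs(pairs$first, pairs$second))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, provenance = provenance),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("<interaction_set> ", nrow(x$pairs), " pairs [", x$provenance, "]\n",
      sep = "")
  invisible(x)
}

#' @export
length.interaction_set <- function(x) nrow(x$pairs)

#' Read a PSI-MI TAB (MITAB 2.5) file into an interaction set
#'
#' Consumes columns 1-2 (interactors A and B), extracting the first
#' `uniprotkb:` token of each. Rows where either interactor carries no
#' uniprotkb accession (e.g. chebi: small molecules) are skipped in the
#' default lenient mode and counted; in strict mode they are an error.
#'
#' @param path MITAB file.
#' @param strict logical; if TRUE a malformed row aborts with its line
#'   number instead of being skipped.
#' @param collapse_isoforms logical; if TRUE isoform suffixes are removed
#'   (`P12345-2` becomes `P12345`).
#' @return An `interaction_set`; attribute `n_skipped` counts skipped rows.
#' @export
read_mitab <- function(path, strict = FALSE, collapse_isoforms = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  # header line is optional in the wild; drop it when present
  if (length(lines) && grepl("^#", lines[1])) lines <- lines[-1]
  if (length(lines) == 0L) {
    out <- interaction_set(data.frame(first = character(),
                                      second = character()),
                           provenance = paste0(path, " (MITAB 2.5)"))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad_shape <- vapply(fields, length, integer(1)) < 2L
  if (any(bad_shape)) {
    if (strict)
      stop("malformed MITAB row (fewer than 2 columns) at line ",
           which(bad_shape)[1])
  }
  grab <- function(cell) {
    if (is.na(cell)) return(NA_character_)
    toks <- strsplit(cell, "|", fixed = TRUE)[[1]]
    hit <- grep("^uniprotkb:", toks, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub("^uniprotkb:", "", hit[1])
  }
  a <- vapply(fields, function(f) if (length(f) >= 1L) grab(f[1]) else NA_character_,
              character(1))
  b <- vapply(fields, function(f) if (length(f) >= 2L) grab(f[2]) else NA_character_,
              character(1))
  ok <- !is.na(a) & !is.na(b) & !bad_shape
  if (strict && any(!ok))
    stop("MITAB row without uniprotkb interactor at line ", which(!ok)[1])
  if (collapse_isoforms) {
    a <- sub("-.*$", "", a)
    b <- sub("-.*$", "", b)
  }
  out <- interaction_set(data.frame(first = a[ok], second = b[ok],
                                    stringsAsFactors = FALSE),
                         provenance = paste0(path, " (MITAB 2.5)"))
  attr(out, "n_skipped") <- sum(!ok)
  if (sum(!ok) > 0) message(sum(!ok), " MITAB row(s) skipped (no uniprotkb interactor)")
  out
}

#' Read a two-column TSV of interacting domain pairs
#'
#' Dialect used by exports of domain-domain contact catalogues
#' (3did/iPfam-style): two Pfam accessions per row, optional header.
#'
#' @param path TSV file.
#' @return An `interaction_set` of Pfam pair accessions.
#' @export
read_domain_pairs <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("domain-pair file needs two columns: ", path)
  # tolerate a header row of non-PF tokens
  if (nrow(df) && !grepl("^PF", df[1, 1]))
    df <- df[-1, , drop = FALSE]
  interaction_set(data.frame(first = df[[1]], second = df[[2]],
                             stringsAsFactors = FALSE),
                  provenance = paste0(path, " (domain pairs TSV)"))
}

#' Subtract known interactions from a candidate pair set
#'
#' Set difference under order-insensitive pair equality: candidates that
#' appear (in either orientation) in the known set are removed. This is the
#' operation that turns a raw NIP dataset into its "stringent" version.
#'
#' @param candidates data.frame with columns `first`, `second` (any
#'   orientation) or an `interaction_set`.
#' @param known an `interaction_set` (or pair data.frame) of known
#'   interactions.
#' @return The surviving rows of `candidates`, canonicalized; attribute
#'   `n_removed` records how many were subtracted.
#' @export
subtract_pairs <- function(candidates, known) {
  cd <- if (inherits(candidates, "interaction_set")) candidates$pairs else
    dedup_pairs(canonical_pairs(candidates$first, candidates$second))
  kn <- if (inherits(known, "interaction_set")) known$pairs else
    canonical_pairs(known$first, known$second)
  keep <- !(pair_keys(cd) %in% pair_keys(kn))
  out <- cd[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Merge two pair sets with overlap accounting
#'
#' @param a,b pair data.frames (columns `first`, `second`) or
#'   `interaction_set`s.
#' @return list with `union` (canonical pair data.frame), `overlap`
#'   (number of shared pairs) and `n_a`, `n_b`.
#' @export
merge_pairs <- function(a, b) {
  pa <- if (inherits(a, "interaction_set")) a$pairs else
    dedup_pairs(canonical_pairs(a$first, a$second))
  pb <- if (inherits(b, "interaction_set")) b$pairs else
    dedup_pairs(canonical_pairs(b$first, b$second))
  ka <- pair_keys(pa); kb <- pair_keys(pb)
  overlap <- sum(kb %in% ka)
  un <- rbind(pa, pb[!(kb %in% ka), , drop = FALSE])
  un <- un[order(un$first, un$second, method = "radix"), , drop = FALSE]
  rownames(un) <- NULL
  list(union = un, overlap = overlap, n_a = nrow(pa), n_b = nrow(pb))
}

#' Percentage of pairs removed by a filtering step
#'
#' Integer percent, rounded half away from zero (so 8.29 -> 8 and
#' 5.5 -> 6), matching how such fractions are conventionally printed.
#'
#' @param n_before,n_after pair counts before and after filtering.
#' @return integer percent.
#' @export
removal_fraction <- function(n_before, n_after) {
  if (any(n_before <= 0)) stop("n_before must be positive")
  if (any(n_after > n_before) || any(n_after < 0))
    stop("need n_before >= n_after >= 0")
  as.integer(floor(100 * (n_before - n_after) / n_before + 0.5))
}

#' Summarize dataset lineages
#'
#' One row per named dataset: size before and after its filtering step and
#' the integer removal percentage, the shape of a content-summary table for
#' a NIP database release.
#'
#' @param lineage named list; each element a list/vector with elements
#'   `n_before` and `n_after`, or a length-2 numeric `c(n_before, n_after)`.
#' @return data.frame with columns `name`, `n_before`, `n_after`,
#'   `removed_fraction_pct`.
#' @export
summarize_datasets <- function(lineage) {
  stopifnot(length(names(lineage)) == length(lineage))
  rows <- lapply(names(lineage), function(nm) {
    el <- lineage[[nm]]
    nb <- if (is.list(el) && !is.null(el$n_before)) el$n_before else el[[1]]
    na <- if (is.list(el) && !is.null(el$n_after)) el$n_after else el[[2]]
    if (nb == 0) {
      warning("dataset '", nm, "' is empty; removal fraction reported as 0")
      pct <- 0L
    } else pct <- removal_fraction(nb, na)
    data.frame(name = nm, n_before = as.integer(nb), n_after = as.integer(na),
               removed_fraction_pct = pct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read a NIP dataset file
#'
#' Tab-separated distribution format: two accession columns in canonical
#' order, the record source (`structure` or `manual`), an evidence column
#' (semicolon-joined `structure:assembly:min_distance` triples for
#' structure-derived records, or a curation tag), and an opaque
#' experimental-method column. Rows are sorted by canonical pair so output
#' is byte-stable. `read_nip_dataset(write_nip_dataset(x))` returns `x`.
#'
#' @param records data.frame with columns `first`, `second`, `source`,
#'   `evidence`, `method`.
#' @param path output/input file path.
#' @return `write_nip_dataset()` returns `path` invisibly;
#'   `read_nip_dataset()` returns the records data.frame.
#' @export
write_nip_dataset <- function(records, path) {
  need <- c("first", "second", "source", "evidence", "method")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  cp <- canonical_pairs(records$first, records$second)
  records$first <- cp$first
  records$second <- cp$second
  records <- records[order(records$first, records$second, method = "radix"),
                     need, drop = FALSE]
  records <- records[!duplicated(pair_keys(records)), , drop = FALSE]
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nip_dataset
#' @export
read_nip_dataset <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("first", "second", "source", "evidence", "method")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed NIP dataset ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  cp <- canonical_pairs(df$first, df$second)
  df$first <- cp$first
  df$second <- cp$second
  df <- df[order(df$first, df$second, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Decode the evidence column of structure-derived NIP records
#'
#' @param evidence character vector of semicolon-joined
#'   `structure:assembly:min_distance` triples.
#' @return data.frame with columns `record` (index into `evidence`),
#'   `structure_id`, `assembly_id`, `min_distance`.
#' @export
parse_evidence <- function(evidence) {
  parts <- strsplit(evidence, ";", fixed = TRUE)
  n <- lengths(parts)
  flat <- strsplit(unlist(parts), ":", fixed = TRUE)
  bad <- vapply(flat, length, integer(1)) != 3L
  if (any(bad)) stop("malformed evidence triple: ", unlist(parts)[bad][1])
  data.frame(record = rep(seq_along(evidence), n),
             structure_id = vapply(flat, `[`, "", 1),
             assembly_id = vapply(flat, `[`, "", 2),
             min_distance = as.numeric(vapply(flat, `[`, "", 3)),
             stringsAsFactors = FALSE)
}
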