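#' Default interaction-verb lexicon
#'
#' Verb lemmas that specifically assert physical interaction or binding,
#' each with a relation-type weight in (0, 1] reflecting how reliably the
#' verb class is interpreted (direct binding evidence ranks highest).
#' Extensible via [score_config()].
#'
#' @return named numeric vector: verb lemma -> weight.
#' @export
default_verb_lexicon <- function() {
  c(bind = 1.0,
    "co-immunoprecipitate" = 1.0,
    interact = 0.9,
    associate = 0.8,
    complex = 0.7,
    "co-localize" = 0.6)
}

#' Configuration of the negated-interaction confidence score
#'
#' The score combines five features of a predicate-argument structure
#' (PAS) and its sentence: argument length, sentence length, relation
#' type, how the negation is expressed, and whether agent and theme are
#' the same entity. See [confidence_score()] for the combination rule.
#'
#' @param verb_lexicon named numeric vector, verb lemma -> weight in
#'   `[0, 1]`; membership defines which relations count as interaction
#'   assertions at all.
#' @param common_negations tokens accepted as ordinary negation markers;
#'   anything else still negates but at reduced confidence.
#' @param weights non-negative weights of the four additive subscores
#'   (`arg`, `sent`, `rel`, `neg`).
#' @param tau_arg,tau_sent exponential decay constants, in tokens, for the
#'   argument-length and sentence-length subscores.
#' @param uncommon_negation_factor subscore assigned to a negation token
#'   outside `common_negations`, in `[0, 1)`.
#' @param same_entity_factor multiplicative penalty in `(0, 1)` applied
#'   when agent and theme are the same entity.
#' @return list of class `score_config`.
#' @export
score_config <- function(verb_lexicon = default_verb_lexicon(),
                         common_negations = c("not", "no", "never", "n't",
                                              "cannot", "neither", "nor",
                                              "without", "fail", "fails",
                                              "failed", "unable"),
                         weights = c(arg = 1, sent = 1, rel = 1, neg = 1),
                         tau_arg = 10, tau_sent = 30,
                         uncommon_negation_factor = 0.5,
                         same_entity_factor = 0.5) {
  if (length(verb_lexicon) == 0L) stop("verb lexicon must be non-empty")
  if (any(verb_lexicon < 0 | verb_lexicon > 1))
    stop("lexicon weights must lie in [0, 1]")
  if (any(weights < 0) || sum(weights) == 0)
    stop("subscore weights must be non-negative with positive sum")
  stopifnot(tau_arg > 0, tau_sent > 0,
            uncommon_negation_factor >= 0, uncommon_negation_factor < 1,
            same_entity_factor > 0, same_entity_factor < 1)
  w <- weights[c("arg", "sent", "rel", "neg")]
  if (any(is.na(w))) stop("weights must be named arg, sent, rel, neg")
  structure(list(verb_lexicon = verb_lexicon,
                 common_negations = common_negations,
                 weights = w, tau_arg = tau_arg, tau_sent = tau_sent,
                 uncommon_negation_factor = uncommon_negation_factor,
                 same_entity_factor = same_entity_factor),
            class = "score_config")
}

#' Read a score configuration from YAML
#'
#' Any field of [score_config()] may be overridden; `verb_lexicon` is a
#' mapping verb -> weight.
#'
#' @param path YAML file.
#' @return a `score_config`.
#' @export
read_score_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$verb_lexicon)) args$verb_lexicon <- unlist(y$verb_lexicon)
  if (!is.null(y$common_negations)) args$common_negations <- unlist(y$common_negations)
  if (!is.null(y$weights)) args$weights <- unlist(y$weights)
  for (nm in c("tau_arg", "tau_sent", "uncommon_negation_factor",
               "same_entity_factor"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(score_config, args)
}

.token_count <- function(x) {
  lengths(strsplit(trimws(x), "\\s+"))
}

# normalize a records input (data.frame or single-record list) to a
# data.frame with the length fields filled in
.as_pas_frame <- function(records) {
  if (!is.data.frame(records)) records <- as.data.frame(records,
                                                        stringsAsFactors = FALSE)
  need <- c("agent", "theme", "relation")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("PAS record(s) missing field(s): ", paste(miss, collapse = ", "))
  if (is.null(records$negation)) records$negation <- NA_character_
  records$negation[!is.na(records$negation) & records$negation == ""] <- NA
  if (is.null(records$sentence)) records$sentence <- NA_character_
  if (is.null(records$agent_len))
    records$agent_len <- .token_count(records$agent)
  if (is.null(records$theme_len))
    records$theme_len <- .token_count(records$theme)
  if (is.null(records$sentence_len)) {
    if (all(is.na(records$sentence)))
      stop("need either sentence text or sentence_len")
    records$sentence_len <- .token_count(records$sentence)
  }
  if (any(records$agent_len < 1 | records$theme_len < 1 |
          records$sentence_len < 1))
    stop("token counts must be >= 1")
  records
}

#' Is a PAS record a negated interaction assertion?
#'
#' True exactly when a negation token is present and the relation verb is
#' a member of the interaction lexicon.
#'
#' @param records one PAS record (named list) or a data.frame of records
#'   with fields `agent`, `theme`, `relation`, `negation` (NA/missing when
#'   absent) and either `sentence` or token-count fields.
#' @param cfg a [score_config()].
#' @return logical vector.
#' @export
is_negated_interaction <- function(records, cfg = score_config()) {
  r <- .as_pas_frame(records)
  !is.na(r$negation) & r$relation %in% names(cfg$verb_lexicon)
}

#' Confidence score of a negated interaction assertion
#'
#' Weighted mean of four subscores, each in `[0, 1]` --- exponential decay
#' in the longer of the two argument lengths, exponential decay in
#' sentence length, the relation-type lexicon weight, and a negation-word
#' subscore (1 for a common negation token, reduced otherwise) ---
#' multiplied by a strict penalty when agent and theme are the same entity
#' (such records are kept: the sentence may still describe another
#' non-interaction). A record with minimal lengths, a top-weight verb, a
#' common negation and distinct entities scores exactly 1.
#'
#' @param records PAS record(s); every record must satisfy
#'   [is_negated_interaction()].
#' @param cfg a [score_config()].
#' @return numeric vector of scores in `[0, 1]`.
#' @export
confidence_score <- function(records, cfg = score_config()) {
  r <- .as_pas_frame(records)
  if (!all(is_negated_interaction(r, cfg)))
    stop("not a negated-interaction candidate (filter with is_negated_interaction first)")
  s_arg <- exp(-(pmax(r$agent_len, r$theme_len) - 1) / cfg$tau_arg)
  s_sent <- exp(-(r$sentence_len - 1) / cfg$tau_sent)
  s_rel <- unname(cfg$verb_lexicon[r$relation])
  s_neg <- ifelse(r$negation %in% cfg$common_negations, 1,
                  cfg$uncommon_negation_factor)
  w <- cfg$weights
  base <- (w["arg"] * s_arg + w["sent"] * s_sent + w["rel"] * s_rel +
             w["neg"] * s_neg) / sum(w)
  same <- r$agent == r$theme
  unname(base * ifelse(same, cfg$same_entity_factor, 1))
}

#' Filter and rank PAS records by confidence
#'
#' Non-candidates (no negation, or relation outside the lexicon) are
#' excluded with a message; candidates are scored and sorted in stable
#' descending score order (ties keep input order). Same-entity records are
#' kept, flagged and penalized.
#'
#' @param records data.frame of PAS records.
#' @param cfg a [score_config()].
#' @return data.frame: the candidate records plus `score`, `kept`
#'   (always TRUE for emitted rows) and `same_entity`, ordered by
#'   descending score.
#' @export
rank_candidates <- function(records, cfg = score_config()) {
  r <- .as_pas_frame(records)
  cand <- is_negated_interaction(r, cfg)
  if (any(!cand))
    message(sum(!cand), " record(s) excluded: not negated interaction assertions")
  r <- r[cand, , drop = FALSE]
  if (nrow(r) == 0L) {
    r$score <- numeric(); r$kept <- logical(); r$same_entity <- logical()
    return(r)
  }
  r$score <- confidence_score(r, cfg)
  r$kept <- TRUE
  r$same_entity <- r$agent == r$theme
  r <- r[order(-r$score, method = "radix"), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Read PAS records from JSON-lines or TSV
#'
#' JSON-lines: one object per line with fields `agent`, `theme`,
#' `relation`, `negation` (null/absent when none), `sentence` and/or the
#' token-count fields. TSV: same fields as header columns, empty
#' `negation` meaning absent.
#'
#' @param path input file.
#' @return data.frame of PAS records.
#' @export
read_pas_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(agent = character(), theme = character(),
                      relation = character(), negation = character(),
                      sentence = character(), stringsAsFactors = FALSE))
  if (grepl("^\\s*\\{", lines[1])) {
    recs <- lapply(lines, jsonlite::fromJSON)
    cols <- unique(unlist(lapply(recs, names)))
    df <- as.data.frame(
      lapply(cols, function(cn)
        unlist(lapply(recs, function(r)
          if (is.null(r[[cn]])) NA else r[[cn]]))),
      stringsAsFactors = FALSE)
    names(df) <- cols
    df
  } else {
    read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  }
}
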