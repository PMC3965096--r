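test_that("canonical pairs ignore orientation and reject empties", {
  cp <- canonical_pairs(c("Q67890", "P12345"), c("P12345", "Q67890"))
  expect_equal(cp$first, c("P12345", "P12345"))
  expect_equal(cp$second, c("Q67890", "Q67890"))
  expect_equal(pair_keys(cp)[1], pair_keys(cp)[2])
  expect_error(canonical_pairs("", "B"), "non-empty")
  expect_equal(nrow(canonical_pairs(character(), character())), 0)
})

test_that("MITAB parsing extracts uniprotkb interactors", {
  f <- withr::local_tempfile(fileext = ".mitab")
  pad <- paste(rep("-", 13), collapse = "\t")
  writeLines(c(
    paste("uniprotkb:P12345", "uniprotkb:Q67890", pad, sep = "\t"),
    paste("chebi:CHEBI:15377", "uniprotkb:Q00001", pad, sep = "\t"),
    paste("intact:EBI-1|uniprotkb:P12345-2", "uniprotkb:P00002", pad,
          sep = "\t")), f)
  s <- suppressMessages(read_mitab(f))
  expect_equal(length(s), 2)
  expect_equal(attr(s, "n_skipped"), 1L)
  expect_true("P12345\tQ67890" %in% pair_keys(s$pairs))
  expect_true("P00002\tP12345-2" %in% pair_keys(s$pairs))

  s2 <- suppressMessages(read_mitab(f, collapse_isoforms = TRUE))
  expect_true("P00002\tP12345" %in% pair_keys(s2$pairs))

  expect_error(read_mitab(f, strict = TRUE), "line 2")
})

test_that("strict mode reports short rows with their line number", {
  f <- withr::local_tempfile(fileext = ".mitab")
  writeLines(c("uniprotkb:P1\tuniprotkb:P2", "justonecolumn"), f)
  expect_error(read_mitab(f, strict = TRUE), "line 2")
  s <- suppressMessages(read_mitab(f))
  expect_equal(length(s), 1)
})

test_that("subtraction is order-insensitive set difference", {
  cand <- data.frame(first = c("P1", "P3"), second = c("P2", "P4"))
  known <- interaction_set(data.frame(first = "P2", second = "P1"))
  out <- subtract_pairs(cand, known)
  expect_equal(nrow(out), 1)
  expect_equal(out$first, "P3")
  expect_equal(attr(out, "n_removed"), 1L)
  # empty known set is the identity
  none <- interaction_set(data.frame(first = character(),
                                     second = character()))
  expect_equal(nrow(subtract_pairs(cand, none)), 2)
})

test_that("subtraction reproduces the curated-dataset stringent count", {
  cand <- synth_pairs(2171)
  known_rows <- rbind(cand[sample(2171, 180), ], synth_pairs(50, "ZZ"))
  out <- subtract_pairs(cand, interaction_set(known_rows))
  expect_equal(nrow(out), 1991)
})

test_that("subtract is idempotent and contained in its input", {
  set.seed(13)
  cand <- synth_pairs(200)
  known <- interaction_set(cand[sample(200, 37), ])
  once <- subtract_pairs(cand, known)
  twice <- subtract_pairs(once, known)
  expect_equal(pair_keys(once), pair_keys(twice))
  expect_true(all(pair_keys(once) %in% pair_keys(cand)))
})

test_that("merging reports the union and overlap of the printed dataset sizes", {
  manual <- synth_pairs(2171, "M")
  shared <- manual[seq_len(36), ]
  structural <- rbind(synth_pairs(4397 - 36, "S"), shared)
  m <- merge_pairs(manual, structural)
  expect_equal(nrow(m$union), 6532)
  expect_equal(m$overlap, 36)
})

test_that("merge handles disjoint and identical sets", {
  a <- synth_pairs(2); b <- synth_pairs(3, "Q")
  m <- merge_pairs(a, b)
  expect_equal(nrow(m$union), 5)
  expect_equal(m$overlap, 0)
  m2 <- merge_pairs(a, a)
  expect_equal(nrow(m2$union), 2)
  expect_equal(m2$overlap, 2)
})

test_that("merge union is commutative, associative, inclusion-exclusion exact", {
  set.seed(8)
  for (i in 1:20) {
    pool <- synth_pairs(80)
    a <- pool[sample(80, sample(10:50, 1)), ]
    b <- pool[sample(80, sample(10:50, 1)), ]
    c_ <- pool[sample(80, sample(10:50, 1)), ]
    mab <- merge_pairs(a, b)
    mba <- merge_pairs(b, a)
    expect_setequal(pair_keys(mab$union), pair_keys(mba$union))
    expect_equal(mab$overlap, mba$overlap)
    expect_equal(nrow(mab$union), mab$n_a + mab$n_b - mab$overlap)
    left <- merge_pairs(mab$union, c_)$union
    right <- merge_pairs(a, merge_pairs(b, c_)$union)$union
    expect_equal(pair_keys(left), pair_keys(right))
  }
})

test_that("removal fractions match the printed filtering percentages", {
  expect_equal(removal_fraction(2171, 1991), 8L)
  expect_equal(removal_fraction(4397, 4161), 5L)
  expect_equal(removal_fraction(6532, 6136), 6L)
  expect_equal(removal_fraction(100, 100), 0L)
  # round half away from zero, not banker's rounding
  expect_equal(removal_fraction(200, 189), 6L)   # 5.5 -> 6
  expect_equal(removal_fraction(200, 195), 3L)   # 2.5 -> 3
  expect_error(removal_fraction(0, 0), "positive")
  expect_error(removal_fraction(5, 6), "n_before >= n_after")
})

test_that("dataset summaries report lineage counts and percentages", {
  s <- summarize_datasets(list(pdb = c(40, 36), merged = c(6532, 6136)))
  expect_equal(s$removed_fraction_pct, c(10L, 6L))
  expect_equal(s$n_before, c(40L, 6532L))
  expect_warning(s0 <- summarize_datasets(list(none = c(0, 0))), "empty")
  expect_equal(s0$removed_fraction_pct, 0L)
})

test_that("NIP dataset files round-trip and normalize pair order", {
  recs <- data.frame(first = c("P2", "A9"), second = c("P1", "B1"),
                     source = c("structure", "manual"),
                     evidence = c("1abc:1:12.000", "curated"),
                     method = c("", "two hybrid"),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_nip_dataset(recs, f)
  back <- read_nip_dataset(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$first, c("A9", "P1"))   # canonical order, sorted
  expect_equal(back$second, c("B1", "P2"))
  expect_equal(back$method[1], "two hybrid")
  # a second round trip is the identity
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_nip_dataset(back, f2)
  expect_equal(read_nip_dataset(f2), back)
  # malformed file: missing columns
  writeLines("first\tsecond\nA\tB", f2)
  expect_error(read_nip_dataset(f2), "missing column")
})

test_that("stringent datasets are subsets of their parents by construction", {
  set.seed(5)
  full <- synth_pairs(120)
  known <- interaction_set(full[sample(120, 25), ])
  stringent <- subtract_pairs(full, known)
  expect_true(all(pair_keys(stringent) %in% pair_keys(full)))
  expect_equal(nrow(stringent), 95)
  expect_equal(removal_fraction(nrow(full), nrow(stringent)), 21L)
})
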