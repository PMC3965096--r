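write_mapping <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("chain mapping loads and rejects conflicting duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mapping(data.frame(structure_id = c("1abc", "1abc"),
                           chain_id = c("A", "B"),
                           accession = c("P11111", "P22222")), f)
  m <- load_chain_mapping(f)
  expect_equal(nrow(m), 2)

  write_mapping(data.frame(structure_id = c("1abc", "1abc"),
                           chain_id = c("A", "A"),
                           accession = c("P11111", "P33333")), f)
  expect_error(load_chain_mapping(f), "conflicting.*1abc")

  # agreeing duplicates are tolerated; empty file gives an empty map
  write_mapping(data.frame(structure_id = c("1abc", "1abc"),
                           chain_id = c("A", "A"),
                           accession = c("P11111", "P11111")), f)
  expect_equal(nrow(load_chain_mapping(f)), 1)
  write_mapping(data.frame(structure_id = character(),
                           chain_id = character(),
                           accession = character()), f)
  expect_equal(nrow(load_chain_mapping(f)), 0)
})

make_results <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(structure_id = r[[1]], assembly_id = r[[2]],
               chain_a = r[[3]], copy_a = as.integer(r[[4]]),
               chain_b = r[[5]], copy_b = as.integer(r[[6]]),
               min_distance = as.numeric(r[[7]]),
               non_interacting = as.numeric(r[[7]]) > 8,
               stringsAsFactors = FALSE)))
}

simple_mapping <- function(sid, chains, accs) {
  df <- data.frame(structure_id = sid, chain_id = chains, accession = accs,
                   stringsAsFactors = FALSE)
  class(df) <- c("chain_mapping", "data.frame")
  df
}

test_that("one observed contact between chain copies falsifies the protein pair", {
  # homodimer of P (two copies) plus Q; Q is close to one P copy only
  res <- make_results(
    list("1x", "1", "A", 1, "A", 2, 3.0),   # P-P self pair, excluded anyway
    list("1x", "1", "A", 1, "B", 1, 6.0),   # P(copy1)-Q in contact
    list("1x", "1", "A", 2, "B", 1, 20.0))  # P(copy2)-Q distant
  map <- simple_mapping("1x", c("A", "B"), c("P1", "Q1"))
  out <- consolidate_protein_pairs(res, map)
  expect_equal(nrow(out), 0)
})

test_that("a distant pair in a single unit yields one NIP record with evidence", {
  res <- make_results(list("1x", "1", "A", 1, "B", 1, 12.0))
  map <- simple_mapping("1x", c("A", "B"), c("P1", "Q1"))
  out <- consolidate_protein_pairs(res, map)
  expect_equal(out$first, "P1")
  expect_equal(out$second, "Q1")
  expect_equal(out$source, "structure")
  ev <- parse_evidence(out$evidence)
  expect_equal(ev$structure_id, "1x")
  expect_equal(ev$min_distance, 12)
})

test_that("a contact in any unit suppresses the pair across all units", {
  res <- make_results(list("1x", "1", "A", 1, "B", 1, 12.0),
                      list("2y", "1", "A", 1, "B", 1, 5.0))
  map <- rbind(simple_mapping("1x", c("A", "B"), c("P1", "Q1")),
               simple_mapping("2y", c("A", "B"), c("P1", "Q1")))
  class(map) <- c("chain_mapping", "data.frame")
  expect_equal(nrow(consolidate_protein_pairs(res, map)), 0)
})

test_that("multi-unit support is accumulated as evidence and self-pairs drop", {
  res <- make_results(list("1x", "1", "A", 1, "B", 1, 12.0),
                      list("2y", "1", "A", 1, "B", 1, 9.5),
                      list("2y", "1", "A", 1, "C", 1, 30.0))
  map <- rbind(simple_mapping("1x", c("A", "B"), c("P1", "Q1")),
               simple_mapping("2y", c("A", "B", "C"), c("P1", "Q1", "P1")))
  class(map) <- c("chain_mapping", "data.frame")
  out <- consolidate_protein_pairs(res, map)
  expect_equal(nrow(out), 1)  # P1-P1 self pair excluded
  ev <- parse_evidence(out$evidence)
  expect_equal(sort(ev$structure_id), c("1x", "2y"))
})

test_that("unmapped chains are dropped with a message, not an error", {
  res <- make_results(list("1x", "1", "A", 1, "B", 1, 12.0),
                      list("1x", "1", "A", 1, "Z", 1, 25.0))
  map <- simple_mapping("1x", c("A", "B"), c("P1", "Q1"))
  expect_message(out <- consolidate_protein_pairs(res, map), "dropped")
  expect_equal(nrow(out), 1)
})

test_that("isoform suffixes are kept verbatim unless collapsed", {
  res <- make_results(list("1x", "1", "A", 1, "B", 1, 12.0))
  map <- simple_mapping("1x", c("A", "B"), c("P12345-2", "P12345"))
  out <- consolidate_protein_pairs(res, map)
  expect_equal(nrow(out), 1)  # distinct accessions as written
  out2 <- consolidate_protein_pairs(res, map, collapse_isoforms = TRUE)
  expect_equal(nrow(out2), 0)  # collapses to a self pair
})

test_that("consolidation is idempotent on its own output", {
  res <- make_results(list("1x", "1", "A", 1, "B", 1, 12.0),
                      list("2y", "1", "A", 1, "B", 1, 16.0),
                      list("2y", "1", "A", 1, "C", 1, 4.0))
  map <- rbind(simple_mapping("1x", c("A", "B"), c("P1", "Q1")),
               simple_mapping("2y", c("A", "B", "C"), c("P1", "Q1", "R1")))
  class(map) <- c("chain_mapping", "data.frame")
  out <- consolidate_protein_pairs(res, map)
  # feed the surviving evidence back in as chain-level results under an
  # identity mapping: nothing may change
  ev <- parse_evidence(out$evidence)
  res2 <- data.frame(structure_id = ev$structure_id,
                     assembly_id = ev$assembly_id,
                     chain_a = out$first[ev$record],
                     copy_a = 1L,
                     chain_b = out$second[ev$record], copy_b = 1L,
                     min_distance = ev$min_distance,
                     non_interacting = ev$min_distance > 8,
                     stringsAsFactors = FALSE)
  ids <- unique(c(res2$chain_a, res2$chain_b))
  idmap <- do.call(rbind, lapply(unique(res2$structure_id), function(s)
    simple_mapping(s, ids, ids)))
  class(idmap) <- c("chain_mapping", "data.frame")
  out2 <- consolidate_protein_pairs(res2, idmap)
  expect_equal(out2, out)
})

test_that("domain expansion is the full cross product, canonical and deduped", {
  dom <- list(P = c("PF00001", "PF00002"), Q = "PF00010", E = character())
  pairs <- data.frame(first = "P", second = "Q")
  out <- expand_domain_pairs(pairs, dom)
  expect_equal(out$first, c("PF00001", "PF00002"))
  expect_equal(out$second, c("PF00010", "PF00010"))
  expect_equal(attr(out, "n_before_dedup"), 2L)

  # empty domain lists contribute nothing
  expect_equal(nrow(expand_domain_pairs(data.frame(first = "P", second = "E"),
                                        dom)), 0)
  # self domain pairs are retained
  self <- expand_domain_pairs(data.frame(first = "P", second = "P2"),
                              list(P = "PF00001", P2 = "PF00001"))
  expect_equal(self$first, "PF00001")
  expect_equal(self$second, "PF00001")
})

test_that("pre-dedup expansion cardinality is the sum of domain-count products", {
  set.seed(31)
  accs <- sprintf("P%02d", 1:12)
  dom <- lapply(setNames(accs, accs), function(a)
    sprintf("PF%05d", sample.int(40, sample(0:4, 1))))
  pairs <- canonical_pairs(sample(accs, 30, TRUE), sample(accs, 30, TRUE))
  pairs <- pairs[pairs$first != pairs$second, ]
  out <- expand_domain_pairs(pairs, dom)
  expected <- sum(vapply(seq_len(nrow(pairs)), function(i)
    length(dom[[pairs$first[i]]]) * length(dom[[pairs$second[i]]]), 0L))
  expect_equal(attr(out, "n_before_dedup"), expected)
  expect_true(all(grepl("^PF[0-9]{5}$", c(out$first, out$second))))
})

test_that("malformed Pfam accessions are rejected when loading", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(accession = "P1", pfam = "PFX1"), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_domain_mapping(f), "malformed Pfam")
})
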