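test_that("FASTA round-trips ids, sequences, and labels", {
  ds <- generate_synthetic(8, c(50, 80), seed = 2)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ds, path)
  back <- read_fasta(path)
  expect_equal(back$id, ds$id)
  expect_equal(back$sequence, ds$sequence)
  expect_equal(back$label, ds$label)

  # id is the header up to the first whitespace
  writeLines(c(">p1 some description", "MKVLAYRR"), path)
  expect_equal(read_fasta(path)$id, "p1")

  # multi-line sequences are concatenated
  writeLines(c(">p1", "MKVL", "AYRR"), path)
  expect_equal(read_fasta(path)$sequence, "MKVLAYRR")
})

test_that("FASTA structural errors carry line numbers and ids", {
  path <- withr::local_tempfile(fileext = ".fasta")

  writeLines(character(0), path)
  expect_error(read_fasta(path), "line 1")

  writeLines(c(">p1", "MKVLAY", ">p2", ">p3", "MKYA"), path)
  expect_error(read_fasta(path), "'p2' has no sequence \\(line 3\\)")

  writeLines(c("MKVLAY", ">p1", "MKYA"), path)
  expect_error(read_fasta(path), "before first header \\(line 1\\)")

  writeLines(c(">dup", "MKVLAY", ">dup", "MKYA"), path)
  expect_error(read_fasta(path), "duplicate record id 'dup'")
})

test_that("label sidecar TSV is accepted", {
  path <- withr::local_tempfile(fileext = ".fasta")
  sidecar <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">p1", "MKVLAY", ">p2", "MKYARR"), path)
  writeLines(c("id\tlabel", "p1\t1", "p2\tnon-binding"), sidecar)
  ds <- read_fasta(path, labels = sidecar)
  expect_equal(as.character(ds$label), c("binding", "non-binding"))
})

test_that("length and X-run filters respect the stated boundaries", {
  recs <- protein_dataset(
    c("short49", "edge50", "long", "x11", "x10", "x11split"),
    c(strrep("A", 49), strrep("A", 50), strrep("A", 80),
      paste0(strrep("A", 30), strrep("X", 11), strrep("A", 30)),
      paste0(strrep("A", 30), strrep("X", 10), strrep("A", 30)),
      paste0(strrep("A", 20), strrep("X", 6), strrep("A", 20),
             strrep("X", 5), strrep("A", 20))))

  by_len <- filter_min_length(recs)
  expect_equal(by_len$removed$id, "short49")
  expect_setequal(c(by_len$kept$id, by_len$removed$id), recs$id)

  by_x <- filter_x_runs(by_len$kept)
  expect_equal(by_x$removed$id, "x11")          # 11 consecutive X removed
  expect_true(all(c("x10", "x11split") %in% by_x$kept$id))

  empty <- filter_min_length(recs[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$removed), 0L)
})

test_that("greedy identity filter keeps first of redundant pairs", {
  recs <- protein_dataset(
    c("a", "a_copy", "unrelated"),
    c(random_sequence(60, 1), random_sequence(60, 1), strrep("KD", 30)))
  kept <- greedy_identity_filter(recs)
  expect_equal(kept$id, c("a", "unrelated"))

  one <- greedy_identity_filter(recs[1, , drop = FALSE])
  expect_equal(one$id, "a")

  # disjoint residue usage: identity ~0, both kept
  pair <- protein_dataset(c("k", "d"), c(strrep("K", 60), strrep("D", 60)))
  expect_equal(nrow(greedy_identity_filter(pair)), 2L)
})

test_that("generate_synthetic is reproducible and correctly shaped", {
  a <- generate_synthetic(212, seed = 5)
  b <- generate_synthetic(212, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 424L)
  expect_equal(as.integer(table(a$label)), c(212L, 212L))
  expect_true(all(nchar(a$sequence) >= 50))

  c_ <- generate_synthetic(10, seed = 6)
  expect_false(identical(a$sequence[1], c_$sequence[1]))

  expect_error(
    generate_synthetic(5, profiles = list(binding = rep(0.1, 20),
                                          non_binding = rep(0.05, 20))),
    "valid distributions")
})

test_that("default profiles produce the stated compositional bias", {
  prof <- default_class_profiles()
  expect_equal(sum(prof$binding), 1)
  expect_equal(sum(prof$non_binding), 1)
  expect_equal(unname(prof$binding[c("K", "R")]), c(0.15, 0.15))

  ds <- generate_synthetic(30, seed = 9)
  kr_frac <- function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% c("K", "R"))
  }
  pos <- vapply(ds$sequence[ds$label == "binding"], kr_frac, numeric(1))
  neg <- vapply(ds$sequence[ds$label == "non-binding"], kr_frac, numeric(1))
  expect_gt(mean(pos), mean(neg))
})

test_that("equal class profiles give matching residue frequencies", {
  prof <- default_class_profiles()
  prof$binding <- prof$non_binding
  ds <- generate_synthetic(40, profiles = prof, seed = 13)
  count_k <- function(seqs) {
    ch <- unlist(strsplit(seqs, ""))
    c(k = sum(ch == "K"), n = length(ch))
  }
  pos <- count_k(ds$sequence[ds$label == "binding"])
  neg <- count_k(ds$sequence[ds$label == "non-binding"])
  # exact binomial 99.9% CI for the pooled rate covers both class rates
  pooled <- (pos["k"] + neg["k"]) / (pos["n"] + neg["n"])
  for (cls in list(pos, neg)) {
    ci <- stats::binom.test(cls[["k"]], cls[["n"]],
                            conf.level = 0.999)$conf.int
    expect_true(pooled >= ci[1] && pooled <= ci[2])
  }
})

test_that("the screening filter composition is idempotent", {
  ds <- generate_synthetic(15, seed = 21)
  pass1 <- filter_x_runs(filter_min_length(ds)$kept)$kept
  pass2 <- filter_x_runs(filter_min_length(pass1)$kept)$kept
  expect_identical(pass1, pass2)
})
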