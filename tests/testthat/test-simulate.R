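test_that("background sampling respects frequencies and the seed", {
  set.seed(1)
  s <- sample_background(100)
  expect_equal(nchar(s), 100)
  expect_true(all(strsplit(s, "")[[1]] %in% AA))
  set.seed(1)
  expect_identical(sample_background(100), s)
  freqs <- setNames(c(1, rep(0, 19)), c("G", setdiff(AA, "G")))
  expect_equal(sample_background(50, freqs), polyG(50))
  expect_error(sample_background(10, c(A = 0.5)), "frequencies")
})

test_that("embedded signals land where the truth record says", {
  set.seed(5)
  bg <- polyG(100)
  can <- embed_signal(bg, "canonical")
  expect_equal(substr(can$sequence, 98, 100), can$motif)
  expect_equal(classify_pts1(can$motif)$label, "canonical")
  nc <- embed_signal(bg, "non_canonical")
  expect_equal(classify_pts1(nc$motif)$label, "non_canonical")
  p2 <- embed_signal(bg, "pts2", pts2_start_range = c(5L, 5L))
  expect_equal(p2$position, 5L)
  expect_true(match_pts2_site(substr(p2$sequence, 5, 13))$strict_match)
  int <- embed_signal(bg, "internal")
  expect_equal(int$motif, "QKL")
  expect_equal(substr(int$sequence, 88, 90), "QKL")
  none <- embed_signal(bg, "none")
  expect_identical(none$sequence, bg)
  expect_true(is.na(none$motif))
  expect_error(embed_signal(polyG(20), "pts2",
                            pts2_start_range = c(30L, 30L)), "too short")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_proteins = 25, seed = 99)
  p1 <- gen_proteome(cfg)
  p2 <- gen_proteome(cfg)
  expect_identical(p1$fasta, p2$fasta)
  expect_identical(p1$truth, p2$truth)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_proteome(p1, f1, t1)
  write_proteome(p2, f2, t2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("configuration validation catches bad fraction vectors", {
  expect_error(simulation_config(fractions = c(canonical = 1)), "named")
  expect_error(simulation_config(
    fractions = c(canonical = 0.5, non_canonical = 0.2, pts2 = 0.2,
                  internal = 0.2, none = 0.2)), "sum to 1")
  expect_error(simulation_config(length_range = c(5, 50)), ">= 20")
})

test_that("empirical signal-kind frequencies match the configured mix", {
  cfg <- simulation_config(n_proteins = 10000, length_range = c(60, 80),
                           pts2_start_range = c(1L, 30L), seed = 202)
  pr <- gen_proteome(cfg)
  counts <- table(factor(pr$truth$kind,
                         levels = names(cfg$fractions)))
  n <- sum(counts)
  for (k in names(cfg$fractions)) {
    p <- cfg$fractions[[k]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(counts[[k]] / n - p), 3 * se + 1e-12)
  }
})

test_that("the annotator recovers every embedded signal on generator output", {
  cfg <- simulation_config(n_proteins = 300, length_range = c(80, 250),
                           seed = 17)
  pr <- gen_proteome(cfg)
  ann <- annotate_proteome(pr$fasta)
  expect_equal(ann$id, pr$truth$id)
  # categories equal the precedence rule applied to embedded + incidental
  # evidence from the truth audit
  expect_equal(ann$summary_category, expected_category(pr$truth))
  # recall of the embedded motifs themselves is exact
  det <- attr(ann, "details")
  for (i in seq_len(nrow(pr$truth))) {
    tr <- pr$truth[i, ]
    if (tr$kind %in% c("canonical", "non_canonical")) {
      expect_equal(ann$terminal_tripeptide[i], tr$motif)
      expect_equal(ann$pts1_label[i], tr$kind)
    } else if (tr$kind == "pts2") {
      m <- det[[i]]$pts2_matches
      expect_true(tr$position %in% m$start[!m$internal])
    } else if (tr$kind == "internal") {
      h <- det[[i]]$internal_hits
      expect_true(any(h$tripeptide == tr$motif &
                        h$end_offset == tr$position))
    }
  }
})
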