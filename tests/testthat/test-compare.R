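# minimal annotation-shaped frame for tally/set logic
fake_ann <- function(labels, categories, tripeptides = NULL,
                     ids = NULL) {
  n <- length(labels)
  data.frame(
    id = if (is.null(ids)) sprintf("p%03d", seq_len(n)) else ids,
    terminal_tripeptide = if (is.null(tripeptides)) rep("GGG", n)
                          else tripeptides,
    pts1_label = labels,
    summary_category = categories,
    stringsAsFactors = FALSE)
}

test_that("category tallies reproduce the reference-catalogue arithmetic", {
  # 74 canonical + 24 non-canonical + 10 no-obvious (3 catalase-internal),
  # plus 19 PTS2 proteins
  ann <- fake_ann(
    labels = c(rep("canonical", 74), rep("non_canonical", 24),
               rep("no_obvious_i", 7), rep("no_obvious_iii", 3),
               rep("no_obvious_iii", 19)),
    categories = c(rep("PTS1_canonical", 74), rep("PTS1_noncanonical", 24),
                   rep("none", 7), rep("internal_PTS", 3),
                   rep("PTS2", 19)))
  t <- tally_categories(ann)
  expect_equal(t$n_total, 127)
  expect_equal(t$n_pts2, 19)
  expect_equal(t$n_pts1_total, 108)
  expect_equal(t$n_pts1_canonical, 74)
  expect_equal(t$n_pts1_noncanonical, 24)
  expect_equal(t$n_no_obvious, 10)
  expect_equal(t$n_catalase_internal, 3)
  expect_equal(t$n_no_pts_strict, 7)
  expect_equal(t$pct_canonical, 68L)
  # conservation: categories sum to the protein count
  expect_equal(t$n_pts2 + t$n_pts1_total, t$n_total)
  empty <- tally_categories(fake_ann(character(0), character(0)))
  expect_equal(empty$n_total, 0)
  expect_true(is.na(empty$pct_canonical))
})

test_that("percent_canonical truncates and is scale-invariant", {
  expect_equal(percent_canonical(74, 108), 68L)
  expect_equal(percent_canonical(55, 97), 56L)  # 56.7 truncates, not rounds
  expect_equal(percent_canonical(0, 10), 0L)
  expect_equal(percent_canonical(740, 1080), percent_canonical(74, 108))
  expect_error(percent_canonical(1, 0), "total")
})

test_that("non-canonical set algebra is correct and symmetric", {
  mk <- function(tps) fake_ann(rep("non_canonical", length(tps)),
                               rep("PTS1_noncanonical", length(tps)),
                               tripeptides = tps)
  a <- mk(c("SSL", "SYM", "SNL"))
  b <- mk(c("SSL", "PKL"))
  s <- noncanonical_sets(a, b)
  expect_equal(s$shared, "SSL")
  expect_setequal(s$unique_a, c("SYM", "SNL"))
  expect_equal(s$unique_b, "PKL")
  expect_length(intersect(s$shared, s$unique_a), 0)
  expect_length(intersect(s$shared, s$unique_b), 0)
  swapped <- noncanonical_sets(b, a)
  expect_equal(swapped$shared, s$shared)
  expect_equal(swapped$unique_a, s$unique_b)
  expect_equal(swapped$unique_b, s$unique_a)
  both_empty <- noncanonical_sets(mk(character(0)), mk(character(0)))
  expect_length(both_empty$shared, 0)
  # PTS2-category proteins do not contribute terminal tripeptides
  dual <- fake_ann("non_canonical", "PTS2", tripeptides = "AHL")
  expect_length(noncanonical_sets(dual, mk("AHL"))$shared, 0)
})

test_that("the six catalogue-shared non-canonical tripeptides intersect fully", {
  six <- c("SSL", "SYM", "SNL", "ASL", "PKL", "PRL")
  mk <- function(tps) fake_ann(rep("non_canonical", length(tps)),
                               rep("PTS1_noncanonical", length(tps)),
                               tripeptides = tps)
  s <- noncanonical_sets(mk(c(six, "SML", "SRY")), mk(c(six, "SNI")))
  expect_setequal(s$shared, six)
  expect_length(s$shared, 6)
})

test_that("no-obvious listings order by sub-category then alphabetically", {
  ann <- fake_ann(
    labels = c("no_obvious_iii", "no_obvious_i", "no_obvious_ii",
               "no_obvious_i", "canonical"),
    categories = c("none", "none", "none", "internal_PTS",
                   "PTS1_canonical"),
    tripeptides = c("VVA", "TNL", "SAK", "GGG", "SKL"))
  l <- no_obvious_listing(ann)
  expect_equal(l$tripeptide, c("GGG", "TNL", "SAK", "VVA"))
  expect_equal(l$label, c("no_obvious_i", "no_obvious_i",
                          "no_obvious_ii", "no_obvious_iii"))
})

test_that("ortholog maps parse comments, drop duplicates, reject bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# reference\ttarget", "reference_id\ttarget_id",
               "At1g01710\tXP_1", "At3g61200\tXP_2", "At1g01710\tXP_1"),
             path)
  map <- read_ortholog_map(path)
  expect_equal(nrow(map), 2)
  expect_equal(names(map), c("reference_id", "target_id"))
  expect_error(read_ortholog_map(tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("At1g01710\t", bad)
  expect_error(read_ortholog_map(bad), "empty")
})

test_that("comparative reports list orphans and serialize round-trippably", {
  mk <- function(tps, ids) fake_ann(rep("non_canonical", length(tps)),
                                    rep("PTS1_noncanonical", length(tps)),
                                    tripeptides = tps, ids = ids)
  a <- mk(c("SSL", "SNL"), c("ref1", "ref2"))
  b <- mk("SSL", "tgt1")
  map <- data.frame(reference_id = "ref1", target_id = "tgt1",
                    stringsAsFactors = FALSE)
  summ <- compare_proteomes(a, b, c("AT", "SL"), map)
  expect_equal(summ$orphans, "ref2")
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  build_report(summ, jp, tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$orphans, "ref2")
  expect_equal(back$shared_noncanonical, "SSL")
  tsv <- read.delim(tp)
  expect_equal(tsv$species, c("AT", "SL"))
  expect_equal(tsv$n_pts1_noncanonical, c(2, 1))
  # empty map orphans every reference entry
  summ2 <- compare_proteomes(a, b, c("AT", "SL"),
                             map[0, , drop = FALSE])
  expect_setequal(summ2$orphans, c("ref1", "ref2"))
  # identical inputs give a symmetric report
  summ3 <- compare_proteomes(a, a, c("AT", "AT2"))
  expect_equal(summ3$tally_a, summ3$tally_b)
  expect_length(summ3$unique_noncanonical_a, 0)
})
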