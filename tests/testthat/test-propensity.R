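make_set <- function(n, n_with, residue, position) {
  base <- "RLAALLAHL"
  out <- character(n)
  for (i in seq_len(n)) {
    s <- base
    if (i <= n_with) substr(s, position, position) <- residue
    else substr(s, position, position) <- "G"
    out[i] <- s
  }
  out
}

test_that("a residue present in every sequence gets propensity 100", {
  np <- make_set(16, 16, "R", 1)
  pt <- compute_propensity(np)
  expect_equal(pt$n, 16)
  r1 <- pt$table[pt$table$position == 1 & pt$table$residue == "R", ]
  expect_equal(r1$count, 16L)
  expect_equal(r1$propensity, 100)
  expect_equal(r1$printed, 100)
})

test_that("propensity values and printing reproduce the published cells", {
  # 11 of 16 at position 9: exact value, printed in full
  p16 <- compute_propensity(make_set(16, 11, "L", 9))
  l9 <- p16$table[p16$table$position == 9 & p16$table$residue == "L", ]
  expect_equal(l9$propensity, 68.75)
  expect_equal(l9$printed, 68.75)
  # 11 of 14 at position 9: truncated to 78.5 (not 78.6)
  p14 <- compute_propensity(make_set(14, 11, "L", 9))
  l9b <- p14$table[p14$table$position == 9 & p14$table$residue == "L", ]
  expect_equal(l9b$propensity, 100 * 11 / 14)
  expect_equal(l9b$printed, 78.5)
  # 7 of 14 at position 5
  p5 <- compute_propensity(make_set(14, 7, "L", 5))
  l5 <- p5$table[p5$table$position == 5 & p5$table$residue == "L", ]
  expect_equal(l5$printed, 50)
})

test_that("the printing rule reproduces every /14 and /16 table value", {
  of14 <- propensity_printed(100 * c(1, 2, 3, 4, 6, 7, 11, 14) / 14)
  expect_equal(of14, c(7.14, 14.2, 21.4, 28.5, 42.8, 50, 78.5, 100))
  of16 <- propensity_printed(100 * c(1, 2, 3, 4, 5, 6, 7, 11, 16) / 16)
  expect_equal(of16, c(6.25, 12.5, 18.75, 25, 31.25, 37.5, 43.75,
                       68.75, 100))
  # printed never drifts more than 0.1 percentage point from full precision
  v <- 100 * (1:97) / 97
  expect_true(all(abs(propensity_printed(v) - v) < 0.1))
})

test_that("counts are conserved per position on random inputs", {
  set.seed(3)
  for (n in c(1, 5, 14, 16, 40)) {
    np <- vapply(seq_len(n), function(i)
      paste(sample(AA, 9, replace = TRUE), collapse = ""), character(1))
    pt <- compute_propensity(np)
    sums <- tapply(pt$table$count, pt$table$position, sum)
    expect_true(all(sums == n))
    psums <- tapply(pt$table$propensity, pt$table$position, sum)
    expect_true(all(abs(psums - 100) < 1e-9))
  }
})

test_that("single-sequence tables are all-100", {
  pt <- compute_propensity("RLAALLAHL")
  expect_true(all(pt$table$propensity == 100))
  expect_equal(nrow(pt$table), 9)
})

test_that("input validation rejects empty sets and wrong lengths", {
  expect_error(compute_propensity(character(0)), "at least one")
  expect_error(compute_propensity(c("RLAALLAHL", "SHORT")), "9 residues")
})

test_that("most_prevalent orders by count with alphabetical ties", {
  np <- c(make_set(11, 11, "L", 9), make_set(3, 3, "I", 9),
          make_set(2, 2, "F", 9))
  pt <- compute_propensity(np)
  expect_equal(most_prevalent(pt, 9), c("L", "I", "F"))
  tie <- compute_propensity(c("RLAALLAHL", "RLAALLAHF", "RLAALLAHA"))
  expect_equal(most_prevalent(tie, 9), c("A", "F", "L"))
  one <- compute_propensity(make_set(4, 4, "H", 8))
  expect_equal(most_prevalent(one, 8), "H")
  expect_error(most_prevalent(pt, 10), "1..9")
})

test_that("format_propensity pairs two species rank-by-rank", {
  a <- compute_propensity(make_set(16, 11, "L", 9))
  b <- compute_propensity(make_set(14, 11, "L", 9))
  single <- format_propensity(a, labels = c("AT", "SL"))
  expect_equal(names(single),
               c("position", "residue_AT", "count_AT", "propensity_AT"))
  expect_true(!is.unsorted(single$position))
  both <- format_propensity(b, a, labels = c("SL", "AT"))
  expect_true(all(c("residue_SL", "residue_AT") %in% names(both)))
  row9 <- both[both$position == 9 & both$residue_SL == "L", ]
  expect_equal(row9$propensity_SL, 78.5)
  expect_equal(row9$propensity_AT, 68.75)
})
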