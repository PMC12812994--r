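# ROR / PRR / chi-square / IC against independent formula oracles and
# algebraic properties.

test_that("ROR matches the direct formula, including the frozen worked example", {
  t1 <- tibble::tibble(a = 10, b = 90, c = 100, d = 9900)
  r <- ror_stat(t1)
  expect_equal(r$ror, 11.0)
  # frozen from independent evaluation: exp(log(11) -+ 1.96 * 0.348155...)
  expect_equal(r$ror_low, 5.5592, tolerance = 1e-4)
  expect_equal(r$ror_high, 21.7656, tolerance = 1e-4)

  # symmetric null table
  r0 <- ror_stat(tibble::tibble(a = 5, b = 5, c = 5, d = 5))
  expect_equal(r0$ror, 1.0)
  expect_equal(log(r0$ror_low), -log(r0$ror_high))

  # doubling the cells keeps the point estimate and narrows the interval
  r2 <- ror_stat(tibble::tibble(a = 20, b = 180, c = 200, d = 19800))
  expect_equal(r2$ror, r$ror)
  expect_lt(r2$ror_high - r2$ror_low, r$ror_high - r$ror_low)
})

test_that("ROR, PRR and chi-square agree with brute-force evaluation on 500 random tables", {
  tabs <- random_tables(500, seed = 99)
  got <- prr_chi2(ror_stat(tabs))
  a <- tabs$a; b <- tabs$b; c <- tabs$c; d <- tabs$d; n <- a + b + c + d
  ror_o <- (a / b) / (c / d)
  se_o <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr_o <- (a * (c + d)) / ((a + b) * c)
  expect_equal(got$ror, ror_o, tolerance = 1e-10)
  expect_equal(got$ror_low, ror_o * exp(-1.96 * se_o), tolerance = 1e-10)
  expect_equal(got$ror_high, ror_o * exp(1.96 * se_o), tolerance = 1e-10)
  expect_equal(got$prr, prr_o, tolerance = 1e-10)
  # chi-square against the textbook implementation
  chi_o <- vapply(seq_len(nrow(tabs)), function(i) {
    suppressWarnings(stats::chisq.test(matrix(c(a[i], b[i], c[i], d[i]), 2,
                                              byrow = TRUE),
                                       correct = TRUE)$statistic)
  }, numeric(1))
  expect_equal(got$chi2, unname(chi_o), tolerance = 1e-10)
})

test_that("zero cells trigger the flagged continuity correction for ROR only", {
  t0 <- tibble::tibble(a = 3, b = 0, c = 10, d = 1000)
  r <- ror_stat(t0)
  expect_true(r$ror_corrected)
  expect_equal(r$ror, (3.5 * 1000.5) / (0.5 * 10.5), tolerance = 1e-12)
  expect_false(ror_stat(tibble::tibble(a = 3, b = 1, c = 10,
                                       d = 1000))$ror_corrected)
})

test_that("PRR is 1 and chi-square about 0 when proportions are equal across rows", {
  t0 <- tibble::tibble(a = 20, b = 180, c = 200, d = 1800)
  got <- prr_chi2(t0)
  expect_equal(got$prr, 1.0)
  expect_lt(got$chi2, 0.05)
})

test_that("IC stays within half a bit of the naive information component on the worked example", {
  t1 <- tibble::tibble(a = 10, b = 90, c = 100, d = 9900)
  got <- bcpnn_ic(t1)
  naive <- log2(10 * 10100 / (100 * 110))  # 3.19879
  expect_equal(naive, 3.19879, tolerance = 1e-5)
  expect_lt(abs(got$ic - naive), 0.5)
  expect_lt(got$ic025, got$ic)
})

test_that("IC is near zero with negative lower bound at independence, and ic025 < ic on random tables", {
  t0 <- tibble::tibble(a = 50, b = 450, c = 450, d = 4050)
  got <- bcpnn_ic(t0)
  expect_lt(abs(got$ic), 0.05)
  expect_lt(got$ic025, 0)
  tabs <- bcpnn_ic(random_tables(500, seed = 7))
  expect_true(all(tabs$ic025 < tabs$ic))
})

test_that("the exact ROR/PRR identity holds and statistics are monotone in a at fixed margins", {
  tabs <- random_tables(200, seed = 13)
  got <- prr_chi2(ror_stat(tabs))
  lhs <- got$ror / got$prr
  rhs <- (got$d / (got$c + got$d)) / (got$b / (got$a + got$b))
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # move one report from (b,c) into (a,d): margins fixed, a increases
  t1 <- tibble::tibble(a = 10, b = 90, c = 100, d = 9900)
  t2 <- tibble::tibble(a = 11, b = 89, c = 99, d = 9901)
  s1 <- bcpnn_ic(prr_chi2(ror_stat(t1)))
  s2 <- bcpnn_ic(prr_chi2(ror_stat(t2)))
  expect_gt(s2$ror, s1$ror)
  expect_gt(s2$prr, s1$prr)
  expect_gt(s2$ic, s1$ic)
})

test_that("statistics depend only on the pair's margins, not on how other drugs and PTs are labelled", {
  u <- shared_universe()
  rec <- u$records
  tab1 <- build_contingency(rec, "bortezomib", "Neuropathy peripheral")
  rec2 <- rec |>
    dplyr::mutate(
      drug = ifelse(drug == "bortezomib", drug, "OTHER"),
      pt = ifelse(pt == "Neuropathy peripheral", pt, "OTHERPT"))
  tab2 <- build_contingency(rec2, "bortezomib", "Neuropathy peripheral")
  expect_identical(tab1[, c("a", "b", "c", "d")],
                   tab2[, c("a", "b", "c", "d")])
})

test_that("contingency construction matches generator bookkeeping and flags empty margins", {
  u <- shared_universe()
  tabs <- faersignal:::contingency_tables(u$records,
                                          c("bortezomib", "carfilzomib",
                                            "ixazomib"))
  truth <- u$sim$truth$pair_counts
  merged <- dplyr::inner_join(tabs, truth, by = c("drug", "pt"),
                              suffix = c("", "_truth"))
  expect_gt(nrow(merged), 50)
  expect_identical(merged$a, merged$a_truth)
  # a + b equals the drug's total report-PT pairs
  drug_tot <- dplyr::count(u$records, drug)
  byd <- tabs |> dplyr::mutate(tot = a + b) |> dplyr::distinct(drug, tot)
  expect_identical(byd$tot, drug_tot$n[match(byd$drug, drug_tot$drug)])
  expect_error(build_contingency(u$records, "no-such-drug", "Nausea"),
               "degenerate")
})
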