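# Time-to-onset: latency extraction, quantiles, Weibull MLE, hazard
# classification, KM and log-rank.

test_that("latency is event date minus earliest therapy start, dropping non-positive or missing", {
  r <- suppressMessages(map_soc(tag_target_reports(dedup_reports(tiny_reports()))))
  rec <- event_records(r)
  ttos <- suppressMessages(extract_tto(rec))
  # 2020-01-01 -> 2020-02-03 is 33 days
  expect_identical(ttos$onset_days[ttos$case_id == "C1"], 33L)
  # an event before therapy start is dropped
  r2 <- r
  r2$events$event_date[r2$events$primaryid == "C3-1"] <- as.Date("2021-01-15")
  ttos2 <- suppressMessages(extract_tto(event_records(r2)))
  expect_false("C3" %in% ttos2$case_id)
})

test_that("generated onset multisets are recovered exactly from the bundle", {
  sim <- synth_generate(synth_config(n_cases = 800, duplicate_rate = 0,
                                     seed = 17))
  rec <- event_records(suppressMessages(
    map_soc(tag_target_reports(dedup_reports(sim$reports)))))
  ttos <- suppressMessages(extract_tto(rec))
  truth <- sim$truth$onsets |>
    dplyr::filter(drug %in% c("bortezomib", "carfilzomib", "ixazomib"))
  expect_identical(nrow(ttos), nrow(truth))
  merged <- dplyr::inner_join(ttos, truth, by = c("case_id", "drug", "pt"))
  expect_identical(nrow(merged), nrow(ttos))
  expect_identical(merged$onset_days.x, merged$onset_days.y)
})

test_that("median and IQR are type-7 quantiles", {
  expect_equal(median_iqr(c(1, 2, 3))$median, 2)
  m <- median_iqr(rep(7, 5))
  expect_true(m$median == 7 && m$q1 == 7 && m$q3 == 7)
  x <- c(1, 5, 9, 13, 40)
  expect_equal(as.numeric(median_iqr(x)),
               unname(stats::quantile(x, c(.5, .25, .75))))
})

test_that("the Weibull MLE matches an independent fitter and is scale-equivariant", {
  set.seed(23)
  x <- stats::rweibull(200, shape = 0.8, scale = 60)
  f <- weibull_mle(x)
  o <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(f$shape_beta, unname(o$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$scale_alpha, unname(o$estimate["scale"]), tolerance = 1e-3)
  f10 <- weibull_mle(x * 10)
  expect_equal(f10$scale_alpha, 10 * f$scale_alpha, tolerance = 1e-4)
  expect_equal(f10$shape_beta, f$shape_beta, tolerance = 1e-4)
  expect_error(weibull_mle(rep(5, 50)), "identical")
  expect_error(weibull_mle(x[1:5]), "at least")
})

test_that("sample medians track the closed-form Weibull median at the bortezomib-like law", {
  inside <- 0L
  for (s in 1:30) {
    set.seed(300 + s)
    x <- stats::rweibull(1000, shape = 0.70, scale = 68.8)
    med <- median_iqr(x)$median
    target <- 68.8 * log(2)^(1 / 0.70)
    if (abs(med - target) / target < 0.15) inside <- inside + 1L
  }
  expect_gte(inside, 27L)
})

test_that("hazard classification follows the shape interval with the boundary going to random", {
  expect_identical(classify_failure_type(0.70, c(0.68, 0.73)), "early")
  expect_identical(classify_failure_type(1.00, c(0.9, 1.1)), "random")
  expect_identical(classify_failure_type(1.5, c(1.2, 1.8)), "wear-out")
  expect_identical(classify_failure_type(0.95, c(0.9, 1.0)), "random")
  expect_identical(classify_failure_type(1.05, c(1.0, 1.1)), "random")
  # stable under tiny perturbations away from the boundary
  expect_identical(classify_failure_type(0.95, c(0.9, 1 - 1e-9)), "early")
})

test_that("the KM cumulative incidence equals the empirical CDF without censoring", {
  ttos <- tibble::tibble(drug = "d", onset_days = c(5, 10, 10, 20))
  km <- km_curve(ttos)
  expect_equal(km$time, c(5, 10, 20))
  expect_equal(km$cum_incidence, c(0.25, 0.75, 1.0))
  one <- km_curve(tibble::tibble(drug = "d", onset_days = 7))
  expect_equal(one$cum_incidence, 1)
  for (s in 1:10) {
    set.seed(400 + s)
    x <- ceiling(stats::rweibull(60, 0.7, 50))
    km <- km_curve(tibble::tibble(drug = "d", onset_days = x))
    ecdf_vals <- stats::ecdf(x)(km$time)
    expect_equal(km$cum_incidence, ecdf_vals, tolerance = 1e-12)
  }
})

test_that("log-rank is null for identical samples and agrees with a permutation oracle", {
  x <- c(3, 8, 15, 30, 60, 90)
  same <- tibble::tibble(drug = rep(c("a", "b"), each = 6),
                         onset_days = rep(x, 2))
  lr <- log_rank(same)
  expect_lt(lr$statistic, 1e-10)
  expect_gt(lr$p_value, 0.99)
  expect_error(log_rank(tibble::tibble(drug = "a", onset_days = x)),
               "two")

  set.seed(55)
  g <- tibble::tibble(
    drug = rep(c("a", "b"), each = 30),
    onset_days = c(ceiling(stats::rweibull(30, 0.7, 40)),
                   ceiling(stats::rweibull(30, 0.7, 90))))
  obs <- log_rank(g)$statistic
  perm <- replicate(2000, {
    shuffled <- g
    shuffled$drug <- sample(g$drug)
    log_rank(shuffled)$statistic
  })
  p_perm <- mean(perm >= obs)
  mc_err <- 3 * sqrt(max(p_perm * (1 - p_perm), 1e-4) / 2000)
  expect_lt(abs(obs |> pchisq(df = 1, lower.tail = FALSE) - p_perm),
            mc_err + 0.02)
})

test_that("the per-drug summary matches the individual fits and the KM curve tracks the generating law", {
  sim <- synth_generate(synth_config(n_cases = 6000, seed = 67))
  rec <- event_records(suppressMessages(
    map_soc(tag_target_reports(dedup_reports(sim$reports)))))
  ttos <- suppressMessages(extract_tto(rec, drugs = "bortezomib"))
  tbl <- tto_summary(ttos)
  f <- weibull_mle(ttos$onset_days)
  expect_equal(tbl$shape_beta, f$shape_beta)
  expect_equal(tbl$scale_alpha, f$scale_alpha)
  expect_identical(tbl$failure_type, f$failure_type)
  # DKW-style agreement between the KM curve and the fitted CDF
  km <- km_curve(ttos)
  fitted_cdf <- stats::pweibull(km$time, f$shape_beta, f$scale_alpha)
  eps <- sqrt(log(2 / 0.01) / (2 * nrow(ttos)))
  expect_lt(max(abs(km$cum_incidence - fitted_cdf)), eps + 0.05)
})
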