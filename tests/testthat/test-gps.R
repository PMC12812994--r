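# Gamma-Poisson Shrinker: hyperparameter recovery, posterior scores,
# quadrature oracle for the posterior quantile.

simulate_gps_cells <- function(n_cells, alpha, beta, seed) {
  set.seed(seed)
  E <- stats::rgamma(n_cells, 5, 0.5) + 0.5
  lambda <- stats::rgamma(n_cells, alpha, beta)
  a <- stats::rpois(n_cells, lambda * E)
  # embed (a, E) in a fourfold-table shape with the right expected count:
  # choose margins so (a+b)(a+c)/N = E
  N <- 1e6
  nd <- round(sqrt(E * N)); ne <- round(E * N / nd)
  tibble::tibble(a = a, b = nd - a, c = ne - a, d = N - nd - ne + a)
}

test_that("a single-gamma world is recovered within 20% by the dominant mixture component", {
  tabs <- simulate_gps_cells(5000, alpha = 2, beta = 4, seed = 21)
  h <- suppressWarnings(gps_fit(tabs))
  # the component carrying most weight must sit near (2, 4)
  comp <- if (h$mix_weight >= 0.5) c(h$alpha1, h$beta1) else c(h$alpha2, h$beta2)
  w <- max(h$mix_weight, 1 - h$mix_weight)
  expect_gt(w, 0.6)
  expect_lt(abs(comp[1] - 2) / 2, 0.2)
  expect_lt(abs(comp[2] - 4) / 4, 0.2)
})

test_that("with no signal (a = round(E)) the fitted mixture concentrates near a rate ratio of 1", {
  set.seed(31)
  E <- stats::rgamma(2000, 5, 0.5) + 0.5
  N <- 1e6
  nd <- round(sqrt(E * N)); ne <- round(E * N / nd)
  a <- round(E)
  tabs <- tibble::tibble(a = a, b = nd - a, c = ne - a, d = N - nd - ne + a)
  h <- suppressWarnings(gps_fit(tabs))
  prior_mean <- h$mix_weight * h$alpha1 / h$beta1 +
    (1 - h$mix_weight) * h$alpha2 / h$beta2
  expect_lt(abs(prior_mean - 1), 0.15)
  scored <- ebgm_stat(tabs, h)
  expect_lt(abs(stats::median(scored$ebgm) - 1), 0.1)
})

test_that("the fit is invariant to cell order", {
  tabs <- simulate_gps_cells(400, alpha = 1.5, beta = 2, seed = 41)
  h1 <- suppressWarnings(gps_fit(tabs))
  h2 <- suppressWarnings(gps_fit(tabs[sample(nrow(tabs)), ]))
  expect_equal(tidy(h1)$estimate, tidy(h2)$estimate, tolerance = 1e-6)
})

test_that("EB05 matches numerical integration of the posterior mixture CDF to 1e-6", {
  tabs <- random_tables(40, seed = 51)
  h <- suppressWarnings(gps_fit(tabs))
  scored <- ebgm_stat(tabs, h)
  E <- faersignal:::gps_expected(tabs)
  for (i in seq_len(10)) {
    q <- faersignal:::gps_posterior_weights(h, tabs$a[i], E[i])
    dens <- function(l) {
      q[1] * stats::dgamma(l, h$alpha1 + tabs$a[i], rate = h$beta1 + E[i]) +
        q[2] * stats::dgamma(l, h$alpha2 + tabs$a[i], rate = h$beta2 + E[i])
    }
    cdf_at <- stats::integrate(dens, 0, scored$eb05[i],
                               rel.tol = 1e-10)$value
    expect_lt(abs(cdf_at - 0.05), 1e-6)
  }
})

test_that("posterior scores are ordered and shrink toward the null in log distance", {
  tabs <- random_tables(500, seed = 61)
  h <- suppressWarnings(gps_fit(tabs))
  scored <- ebgm_stat(tabs, h)
  expect_true(all(scored$eb05 < scored$ebgm))
  # null-table score is near 1 under a diffuse-ish fitted prior
  E <- faersignal:::gps_expected(tabs)
  null_like <- which(abs(tabs$a - E) < 0.5)
  if (length(null_like) > 0) {
    expect_lt(abs(log(scored$ebgm[null_like[1]])), log(2))
  }
  # shrinkage: log-distance to 1 does not exceed the observed one plus the
  # prior's own offset
  offset <- abs(log(h$mix_weight * h$alpha1 / h$beta1 +
                      (1 - h$mix_weight) * h$alpha2 / h$beta2)) + 0.5
  expect_true(all(abs(log(scored$ebgm)) <=
                    abs(log(tabs$a / E)) + offset))
})
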