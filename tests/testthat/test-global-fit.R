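test_that("noiseless single-exponential data are recovered exactly", {
  t <- seq(1, 150, by = 2)
  wl <- seq(500, 700, by = 10)
  das <- 0.1 * exp(-(wl - 649)^2 / 1800)
  off <- 0.02 * exp(-(wl - 600)^2 / 2000)
  m <- trmatrix(t, wl, outer(exp(-t / 18), das) + rep(1, length(t)) %o% off)
  f <- global_exp_fit(m, n_exp = 1, with_offset = TRUE)
  expect_equal(unname(coef(f)), 18, tolerance = 1e-6)
  expect_equal(f$das[1, ], das, tolerance = 1e-6)
  expect_equal(f$offset$values, off, tolerance = 1e-6)
  expect_lt(f$residual_rms, 1e-8)
})

test_that("noiseless biexponential data are recovered exactly", {
  t <- exp(seq(log(1), log(1500), length.out = 50))
  wl <- seq(500, 700, by = 20)
  d1 <- 0.05 * sin(wl / 40)
  d2 <- 0.08 * cos(wl / 55)
  m <- trmatrix(t, wl, outer(exp(-t / 14), d1) + outer(exp(-t / 385), d2))
  f <- global_exp_fit(m, n_exp = 2, with_offset = TRUE)
  expect_equal(unname(coef(f)), c(14, 385), tolerance = 1e-6)
  # taus sorted ascending with amplitudes permuted accordingly
  expect_equal(f$das[1, ], d1, tolerance = 1e-5)
  expect_equal(f$das[2, ], d2, tolerance = 1e-5)
})

test_that("variable projection matches a dense grid-search oracle", {
  set.seed(21)
  t <- seq(2, 120, length.out = 18)
  wl <- seq(600, 700, length.out = 12)
  m <- trmatrix(t, wl, outer(exp(-t / 25), runif(12, 0.05, 0.2)) +
                  matrix(rnorm(18 * 12, 0, 2e-3), 18, 12))
  f <- global_exp_fit(m, n_exp = 1, with_offset = TRUE)
  # oracle: log grid at 0.1% spacing via an independent lm.fit path
  taus <- exp(seq(log(5), log(100), by = log(1.001)))
  rss <- vapply(taus, function(tau) oracle_rss(tau, t, m$values), numeric(1))
  tau_oracle <- taus[which.min(rss)]
  expect_equal(unname(coef(f)), tau_oracle, tolerance = 2e-3)
  expect_lte(f$convergence$rss, min(rss) + 1e-12)
})

test_that("two-exponential optimum matches the grid oracle on small matrices", {
  set.seed(22)
  t <- exp(seq(log(1), log(1200), length.out = 20))
  wl <- seq(600, 700, length.out = 10)
  m <- trmatrix(t, wl,
                outer(exp(-t / 14), runif(10, -0.1, 0.1)) +
                outer(exp(-t / 385), runif(10, 0.05, 0.15)) +
                matrix(rnorm(200, 0, 1e-3), 20, 10))
  f <- global_exp_fit(m, n_exp = 2, with_offset = FALSE)
  # coarse 2-D grid, then 0.1% refinement around the coarse optimum
  coarse <- exp(seq(log(1), log(2000), length.out = 60))
  rss_c <- outer(seq_along(coarse), seq_along(coarse), Vectorize(function(i, j)
    if (coarse[i] >= coarse[j]) Inf
    else oracle_rss(c(coarse[i], coarse[j]), t, m$values, with_offset = FALSE)))
  best <- arrayInd(which.min(rss_c), dim(rss_c))
  refine <- function(center) center * exp(seq(-0.15, 0.15, by = log(1.001)))
  g1 <- refine(coarse[best[1]]); g2 <- refine(coarse[best[2]])
  rss_f <- outer(seq_along(g1), seq_along(g2), Vectorize(function(i, j)
    oracle_rss(c(g1[i], g2[j]), t, m$values, with_offset = FALSE)))
  bf <- arrayInd(which.min(rss_f), dim(rss_f))
  expect_equal(unname(coef(f)), c(g1[bf[1]], g2[bf[2]]), tolerance = 3e-3)
})

test_that("fit residual never exceeds the truth's residual", {
  set.seed(23)
  for (i in 1:5) {
    t <- exp(seq(log(1), log(1500), length.out = 25))
    wl <- seq(600, 680, length.out = 8)
    truth <- c(14, 385)
    Y <- outer(exp(-t / truth[1]), runif(8, -0.1, 0.1)) +
      outer(exp(-t / truth[2]), runif(8, 0.05, 0.15)) +
      matrix(rnorm(200, 0, 1e-3), 25, 8)
    m <- trmatrix(t, wl, Y)
    f <- global_exp_fit(m, n_exp = 2, with_offset = FALSE)
    expect_lte(f$convergence$rss,
               oracle_rss(truth, t, Y, with_offset = FALSE) + 1e-12)
  }
})

test_that("parameter recovery holds across seeded noisy replicates", {
  t <- exp(seq(log(1), log(1500), length.out = 40))
  wl <- seq(600, 700, by = 10)
  d1 <- 0.08 * exp(-(wl - 705)^2 / 1500)
  d2 <- 0.06 * exp(-(wl - 650)^2 / 1500)
  err <- replicate(20, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    Y <- outer(exp(-t / 14), d1) + outer(exp(-t / 385), d2) +
      matrix(rnorm(length(t) * length(wl), 0, 1e-3), length(t))
    f <- global_exp_fit(trmatrix(t, wl, Y), n_exp = 2, with_offset = FALSE)
    abs(coef(f) - c(14, 385)) / c(14, 385)
  })
  expect_lt(stats::median(err[1, ]), 0.05)
  expect_lt(stats::median(err[2, ]), 0.05)
})

test_that("evaluate_model agrees with the closed form", {
  t <- seq(1, 150, by = 2)
  wl <- seq(500, 700, by = 10)
  das <- 0.1 * exp(-(wl - 649)^2 / 1800)
  off <- 0.02 * exp(-(wl - 600)^2 / 2000)
  m <- trmatrix(t, wl, outer(exp(-t / 18), das) + rep(1, length(t)) %o% off)
  f <- global_exp_fit(m, n_exp = 1, with_offset = TRUE)
  # on the fit grid: equals the stored model evaluation
  expect_equal(evaluate_model(f, t)$values, f$fitted$values, tolerance = 1e-12)
  expect_equal(predict(f)$values, f$fitted$values, tolerance = 1e-12)
  # at t -> infinity: the offset spectrum
  expect_equal(evaluate_model(f, 1e9)$values[1, ], f$offset$values,
               tolerance = 1e-8)
  # at t = tau: offset + DAS/e
  expect_equal(evaluate_model(f, f$taus[1])$values[1, ],
               f$offset$values + f$das[1, ] / exp(1), tolerance = 1e-8)
})

test_that("degenerate tau pairs and undersized data are reported", {
  t <- seq(1, 60, by = 1)
  wl <- c(500, 600, 700)
  Y <- outer(exp(-t / 20), c(0.1, 0.2, 0.1))
  # single-exponential data fitted with two exponentials: taus collapse
  f <- global_exp_fit(trmatrix(t, wl, Y), n_exp = 2, with_offset = FALSE)
  expect_true(any(grepl("degenerate", f$convergence$warnings)) ||
                f$taus[2] / f$taus[1] >= 1.5)
  expect_error(global_exp_fit(trmatrix(1:3, wl, Y[1:3, ]), n_exp = 1),
               "at least")
  expect_error(global_exp_fit(trmatrix(t, wl, Y), n_exp = 3), "1 or 2")
  expect_error(global_exp_fit(trmatrix(t, wl, Y), tau_bounds = c(5, 2)),
               "tau_bounds")
})
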