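make_curve <- function(x, y) {
  df <- data.frame(control = x, s_mean = y, s_se = 0)
  structure(list(curve = df), class = "sweep_curve")
}

test_that("locate_peak refines, breaks ties left, and flags boundaries", {
  # exact symmetric triangle: apex recovered
  x <- seq(0, 1, by = 0.1)
  pk <- locate_peak(make_curve(x, 1 - abs(x - 0.5)))
  expect_equal(pk$x, 0.5, tolerance = 1e-8)
  expect_false(pk$unbracketed)
  # flat plateau: smallest control value wins
  pk2 <- locate_peak(make_curve(x, c(0, 1, 2, 2, 2, 2, 1, 0, 0, 0, 0)))
  expect_equal(pk2$index, 3)
  # noisy parabola: vertex recovered within tolerance
  set.seed(2)
  xx <- seq(-1, 1, length.out = 21)
  yy <- 5 - 3 * (xx - 0.21)^2 + rnorm(21, sd = 0.01)
  pk3 <- locate_peak(make_curve(xx, yy))
  expect_lt(abs(pk3$x - 0.21), 0.06)
  # boundary maximum is unbracketed
  pk4 <- locate_peak(make_curve(x, x))
  expect_true(pk4$unbracketed)
  expect_error(locate_peak(make_curve(1:3, 1:3)), ">= 5")
})

test_that("fit_powerlaw recovers exponents exactly and under noise", {
  x <- c(1, 2, 4, 8, 16, 32)
  # noiseless power laws recover the generating exponent to machine
  # precision (summary.lm warns about the perfect fit; that is the point)
  f <- suppressWarnings(fit_powerlaw(x, x^2))
  expect_equal(f$exponent, 2, tolerance = 1e-12)
  expect_lt(f$se, 1e-10)
  fh <- suppressWarnings(fit_powerlaw(x, 3 * x^0.5))
  expect_equal(fh$exponent, 0.5, tolerance = 1e-12)
  expect_equal(fh$prefactor, 3, tolerance = 1e-9)
  set.seed(14)
  ok <- 0
  for (i in 1:10) {
    y <- x^0.82 * exp(rnorm(6, sd = 0.05))
    fn <- fit_powerlaw(x, y)
    if (abs(fn$exponent - 0.82) < 2 * fn$se) ok <- ok + 1
  }
  expect_gte(ok, 8) # ~95% coverage expected
  expect_error(fit_powerlaw(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_powerlaw(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("sweep_control rejects degenerate designs", {
  expect_error(sweep_control("se", grid = c(0.2, 0.2, 0.3, 0.4, 0.5),
                             size = 8, fixed = 0.5), "increasing")
  expect_error(sweep_control("se", grid = c(0.1, 0.2, 0.3), size = 8,
                             fixed = 0.5), ">= 5")
  expect_error(sweep_control("se", grid = seq(0.1, 0.5, 0.1), size = 8,
                             n_realizations = 1, fixed = 0.5), "realizations")
})

test_that("tau and s* are recovered within uncertainty across tau values", {
  set.seed(501)
  for (tau in c(2.0, 2.2, 2.5)) {
    censuses <- lapply(1:25, function(i) {
      sample_census(synth_spec(tau = tau, s_star = 80, N = 8000),
                    seed = 900 * tau + i)
    })
    f <- fit_cluster_ccdf(censuses, n_boot = 25)
    tol <- 2 * sqrt(f$tau_se^2 + f$tau_systematic^2)
    expect_lt(abs(f$tau - tau), tol)
    expect_lt(abs(f$s_star_fit - 80) / 80, 0.5)
    expect_true(f$power_law_ok)
  }
})

test_that("a pure power law fits with a diverging cutoff", {
  censuses <- lapply(1:25, function(i) {
    sample_census(synth_spec(tau = 2.5, s_star = Inf, N = 8000),
                  seed = 7000 + i)
  })
  f <- fit_cluster_ccdf(censuses, n_boot = 20)
  expect_lt(abs(f$tau - 2.5), 2 * sqrt(f$tau_se^2 + f$tau_systematic^2))
  expect_gt(f$s_star_fit, f$fit_window[2]) # no material cutoff in-window
})

test_that("geometric cluster sizes are flagged as non-power-law", {
  geo <- lapply(1:40, function(i) {
    set.seed(i)
    cluster_census(rgeom(600, 0.05) + 1)
  })
  g <- fit_cluster_ccdf(geo, n_boot = 0)
  expect_false(g$power_law_ok)
})

test_that("the line method reports the plotted slope", {
  censuses <- lapply(1:25, function(i) {
    sample_census(synth_spec(tau = 2.5, s_star = Inf, N = 8000),
                  seed = 7000 + i)
  })
  f <- fit_cluster_ccdf(censuses, method = "line", n_boot = 0)
  expect_equal(f$tau, 1 + abs(f$slope))
  # steeper than the asymptotic -(tau-1): retains discreteness/cutoff bias
  expect_lt(f$slope, -1.4)
})

test_that("universality assignment matches reference triples", {
  expect_equal(classify_universality(2.055, 0.896, 0.948)$class,
               "2D Percolation")
  expect_equal(classify_universality(2.5, 1 / 3, 2 / 3)$class,
               "Mean-Field Percolation")
  d <- classify_universality(2.5, 1 / 3, 2 / 3)$distances
  expect_equal(unname(d["Mean-Field Percolation"]), 0, tolerance = 1e-12)
  # measured MEF triple classifies as 2D
  mef <- classify_universality(2.01, 0.82, 1.01)
  expect_equal(mef$class, "2D Percolation")
  expect_equal(length(mef$distances), 3)
  expect_error(classify_universality(NA, 1, 1), "finite")
})

test_that("mean cluster size and N2 peak together on both models", {
  sw_se <- sweep_control("se", grid = seq(0.08, 0.48, by = 0.05), size = 24,
                         n_realizations = 6, seed = 61, fixed = 0.6,
                         keep_censuses = FALSE)
  i_s <- locate_peak(sw_se, "s")$index
  i_n2 <- locate_peak(sw_se, "N2")$index
  expect_lte(abs(i_s - i_n2), 1)
  Ne <- 800
  sw_ab <- sweep_control("ab", grid = exp(seq(log(0.1), log(2),
                                              length.out = 9)) / Ne,
                         size = Ne, n_realizations = 6, seed = 62,
                         fixed = 0.01, keep_censuses = FALSE)
  j_s <- locate_peak(sw_ab, "s")$index
  j_n2 <- locate_peak(sw_ab, "N2")$index
  expect_lte(abs(j_s - j_n2), 1)
})
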