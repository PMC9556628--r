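test_that("synth_spec validates its parameters", {
  expect_error(synth_spec(tau = 1), "tau")
  expect_error(synth_spec(s_star = 2, s0 = 5), "s_star")
  expect_error(synth_spec(base_intensity = 0), "base_intensity")
  sp <- synth_spec(tau = 2.2, s_star = 50, N = 500)
  expect_s3_class(sp, "synth_spec")
})

test_that("the census sampler is deterministic and mass-targeted", {
  sp <- synth_spec(tau = 2, s_star = 40, N = 2000)
  a <- sample_census(sp, seed = 5)
  b <- sample_census(sp, seed = 5)
  expect_identical(a$sizes, b$sizes)
  expect_lt(abs(a$N - 2000) / 2000, 0.2)
  expect_identical(attr(a, "spec")$tau, 2)
  # degenerate cutoffs s* = s0: mass piles up at and just above s0
  d <- sample_census(synth_spec(tau = 2, s_star = 5, s0 = 5, N = 400),
                     seed = 6)
  expect_equal(min(d$sizes), 5L)
  expect_equal(as.integer(names(which.max(table(d$sizes)))), 5L)
  expect_gt(mean(d$sizes <= 10), 0.8)
})

test_that("sampled sizes follow the analytic distribution", {
  set.seed(9)
  sp <- synth_spec(tau = 2.5, s_star = Inf, N = 2e5)
  sizes <- sample_census(sp, seed = 10)$sizes
  # empirical CCDF slope ~ -(tau - 1) over a decade away from discreteness
  su <- sort(unique(sizes[sizes >= 5 & sizes <= 200]))
  ccdf_emp <- vapply(su, function(v) mean(sizes >= v), numeric(1))
  f <- fit_powerlaw(su, ccdf_emp)
  expect_lt(abs(f$exponent - (-1.5)), 0.12)
  # Kolmogorov-Smirnov distance against the exact discrete CDF
  smax <- max(sizes)
  w <- (1:smax)^(-2.5)
  cdf_exact <- cumsum(w) / sum(w)
  cdf_emp <- vapply(1:smax, function(v) mean(sizes <= v), numeric(1))
  expect_lt(max(abs(cdf_emp - cdf_exact)), 0.02)
})

test_that("random-graph censuses behave at the degree extremes", {
  expect_equal(er_graph_census(200, 0, seed = 1)$sizes, rep(1L, 200))
  dense <- er_graph_census(500, 6, seed = 2)
  expect_gt(dense$N_g / dense$N, 0.95) # giant component swallows the graph
  expect_error(er_graph_census(1, 1), "invalid")
})

test_that("noiseless rendering round-trips the census exactly", {
  sp <- synth_spec(tau = 2, s_star = 25, N = 400, noise_sd = 0,
                   halo_width = 0, intensity_jitter = 0)
  census <- sample_census(sp, seed = 20)
  r <- render_mask(census, sp, seed = 21)
  for (th in c(0.05, 0.3, sp$base_intensity)) {
    got <- mass_census(binarize(r$image, th))
    expect_identical(got$sizes, census$sizes)
  }
  expect_identical(r$ground_truth$sizes, census$sizes)
})

test_that("halo perturbs masses with threshold but never merges clusters", {
  sp <- synth_spec(tau = 2, s_star = 25, N = 400, noise_sd = 0,
                   halo_width = 1, intensity_jitter = 0)
  census <- sample_census(sp, seed = 30)
  r <- render_mask(census, sp, seed = 31)
  lo <- mass_census(binarize(r$image, 0.2 * sp$base_intensity)) # halo in
  hi <- mass_census(binarize(r$image, 0.6 * sp$base_intensity)) # halo out
  expect_equal(length(lo$sizes), length(hi$sizes)) # same cluster count
  expect_gt(lo$N, hi$N) # low threshold adds halo mass
  expect_identical(hi$sizes, census$sizes)
})

test_that("lattice rendering reproduces the non-wrapping lattice census", {
  run <- se_simulate(8, 0.35, 0.5, burn_in_sweeps = 30, n_samples = 1,
                     seed = 41, return_configs = TRUE)
  config <- run$configs[[1]]
  sp <- synth_spec(noise_sd = 0, halo_width = 0)
  r <- render_mask(config, sp, pixel_scale = 2)
  truth <- se_census(config, wrap = FALSE)
  got <- mass_census(binarize(r$image, 0.5))
  expect_equal(length(got$sizes), length(truth$sizes))
  # pixel mass: 4 per node plus 2 per drawn bond, summed over clusters
  edges <- se_edges(config, wrap = FALSE)
  expect_equal(got$N, 4 * config$N + 2 * nrow(edges))
  # singleton lattice clusters appear as isolated 2x2 blocks
  expect_equal(sum(got$sizes == 4), sum(truth$sizes == 1))
})

test_that("ensembles span the requested mass decade with ground truth", {
  set.seed(50)
  ens <- synth_ensemble(10, N_range = c(200, 2000), tau = 2,
                        spec = synth_spec(noise_sd = 0, halo_width = 0),
                        seed = 51, render = FALSE)
  masses <- vapply(ens, function(e) as.numeric(e$ground_truth$N), numeric(1))
  expect_gt(max(masses) / min(masses), 3)
  expect_true(attr(ens, "mass_range_ok"))
  expect_true(all(vapply(ens, function(e) inherits(e$spec, "synth_spec"),
                         logical(1))))
  expect_warning(
    synth_ensemble(10, N_range = c(500, 900), seed = 5, render = FALSE),
    "factor 3")
  expect_error(synth_ensemble(5, seed = 1), ">= 10")
})
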