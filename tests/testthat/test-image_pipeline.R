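# a small fixture: two rectangular blobs with graded halo intensities
two_blob_image <- function() {
  img <- matrix(0, 20, 20)
  img[3:6, 3:7] <- 0.9
  img[12:16, 10:14] <- 0.8
  img[2, 3:7] <- 0.3 # halo row above blob 1
  img[11, 10:14] <- 0.3
  img
}

test_that("binarize thresholds by intensity", {
  img <- matrix(0.2, 4, 4)
  expect_false(any(binarize(img, 0.5)))
  expect_true(all(binarize(img, 0.2))) # threshold at the minimum intensity
  expect_error(binarize(array(0, c(2, 2, 2)), 0.5), "2D")
  m <- binarize(two_blob_image(), 0.5)
  expect_equal(sum(m), 4 * 5 + 5 * 5) # exactly the two blobs
})

test_that("mass_census uses 8-connectivity and conserves mass", {
  # diagonal-only touch joins clusters
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(mass_census(m)$sizes, 2L)
  # single foreground pixel
  m1 <- matrix(FALSE, 3, 3); m1[2, 2] <- TRUE
  expect_equal(mass_census(m1)$sizes, 1L)
  # 4x4 checkerboard: all 8 TRUE cells diagonally connected
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  expect_equal(mass_census(cb)$sizes, 8L)
  expect_null(mass_census(matrix(FALSE, 3, 3)))
  set.seed(33)
  for (i in 1:5) {
    m <- matrix(runif(400) < 0.4, 20, 20)
    cc <- mass_census(m)
    expect_equal(cc$N, sum(m)) # masses sum to the foreground count
  }
})

test_that("mass_census agrees with an igraph labeling oracle", {
  set.seed(44)
  for (i in 1:10) {
    m <- matrix(runif(15 * 15) < 0.35, 15, 15)
    if (!any(m)) next
    fg <- which(m)
    coord <- cbind(((fg - 1) %% 15) + 1, ((fg - 1) %/% 15) + 1)
    n <- length(fg)
    edges <- NULL
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a < b && max(abs(coord[a, ] - coord[b, ])) <= 1)
        edges <- rbind(edges, c(a, b))
    }
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    expect_equal(mass_census(m)$sizes,
                 sort(as.integer(igraph::components(g)$csize),
                      decreasing = TRUE))
  }
})

test_that("threshold ensembles propagate threshold spread", {
  img <- two_blob_image()
  net <- threshold_ensemble(img, thresholds = c(0.25, 0.5, 0.85))
  expect_s3_class(net, "image_network")
  # halo included at the lowest threshold only: mass decreases in threshold
  expect_true(all(diff(net$observables$N) <= 0))
  # summary matches direct recomputation
  expect_equal(net$summary$mean[net$summary$observable == "N"],
               mean(net$observables$N))
  expect_equal(net$summary$sd[net$summary$observable == "N"],
               sd(net$observables$N))
  # binary image: zero spread across interior thresholds
  bin <- matrix(0, 10, 10); bin[2:4, 2:4] <- 1
  nb <- threshold_ensemble(bin, thresholds = c(0.3, 0.6, 0.9))
  expect_equal(nb$summary$sd[nb$summary$observable == "N"], 0)
  # out-of-range thresholds are flagged
  nf <- threshold_ensemble(img, thresholds = c(0.5, 2))
  expect_equal(nf$flagged, c(FALSE, TRUE))
  expect_error(threshold_ensemble(img, thresholds = 0.5), ">= 2")
})

test_that("mass-ranked grouping pools equal-count groups", {
  set.seed(55)
  nets <- lapply(1:10, function(i) {
    r <- render_mask(sample_census(synth_spec(tau = 2, s_star = 20,
                                              N = 150 + 40 * i)),
                     synth_spec(noise_sd = 0, halo_width = 0), seed = i)
    threshold_ensemble(r$image, thresholds = c(0.3, 0.5), id = paste(i))
  })
  groups <- rank_group_ccdf(nets, n_groups = 5)
  expect_length(groups, 5)
  expect_equal(vapply(groups, `[[`, numeric(1), "n_networks"), rep(2, 5))
  masses <- vapply(groups, `[[`, numeric(1), "mean_mass")
  expect_true(all(diff(masses) > 0))
  # identical networks give identical group CCDFs
  same <- rank_group_ccdf(rep(nets[3], 6), n_groups = 3)
  expect_equal(same[[1]]$ccdf, same[[3]]$ccdf)
  expect_error(rank_group_ccdf(nets[1:3], n_groups = 5), "fewer")
})

test_that("group cutoffs grow with mass when built in", {
  set.seed(66)
  ens <- synth_ensemble(12, N_range = c(400, 4000), tau = 2,
                        s_star_coef = 0.08, s_star_exp = 1,
                        spec = synth_spec(noise_sd = 0.02), seed = 8,
                        render = TRUE)
  nets <- lapply(seq_along(ens), function(i) {
    threshold_ensemble(ens[[i]]$image, quantiles = c(0.4, 0.6),
                       id = paste(i))
  })
  groups <- rank_group_ccdf(nets, n_groups = 3)
  # the largest observed cluster grows from lightest to heaviest group
  tails <- vapply(groups, function(g) max(g$ccdf$s), numeric(1))
  expect_gt(tails[3], tails[1])
})

test_that("sliding-window scaling handles degenerate collections", {
  set.seed(77)
  r <- render_mask(sample_census(synth_spec(tau = 2, s_star = 30, N = 500)),
                   synth_spec(noise_sd = 0, halo_width = 0), seed = 1)
  net <- threshold_ensemble(r$image, thresholds = c(0.3, 0.5))
  same <- rep(list(net), 8)
  w <- testthat::capture_warnings(
    out <- sliding_window_scaling(same, window = 4))
  expect_true(any(grepl("dynamic range", w)))
  expect_null(out$fits$omega1)
  # window equal to the whole collection leaves a single point
  w2 <- testthat::capture_warnings(
    out2 <- sliding_window_scaling(same, window = 8))
  expect_true(any(grepl("too few|dynamic", w2)))
  expect_error(sliding_window_scaling(same, window = 9), "larger")
  expect_error(sliding_window_scaling(same, window = 1), ">= 2")
})

test_that("built-in N2 ~ N scaling is recovered from rendered images", {
  set.seed(88)
  ens <- synth_ensemble(18, N_range = c(300, 3500), tau = 2,
                        s_star_coef = 0.08, s_star_exp = 1,
                        spec = synth_spec(noise_sd = 0.02), seed = 19,
                        render = TRUE)
  nets <- lapply(seq_along(ens), function(i) {
    threshold_ensemble(ens[[i]]$image, quantiles = c(0.4, 0.6, 0.8),
                       id = paste(i))
  })
  sws <- sliding_window_scaling(nets, window = 6)
  f1 <- sws$fits$omega1
  expect_false(is.null(f1))
  expect_lt(abs(f1$exponent - 1), max(2 * f1$se, 0.25))
  # omega2 and omega3 measure the same scaling (both susceptibility proxies)
  f2 <- sws$fits$omega2; f3 <- sws$fits$omega3
  if (!is.null(f2) && !is.null(f3))
    expect_lt(abs(f2$exponent - f3$exponent),
              3 * sqrt(f2$se^2 + f3$se^2) + 0.4)
})

test_that("images round-trip through TIFF and PNG", {
  img <- two_blob_image()
  tp <- withr::local_tempfile(fileext = ".tif")
  pp <- withr::local_tempfile(fileext = ".png")
  write_network_image(img, tp)
  write_network_image(img, pp)
  expect_equal(read_network_image(tp), img, tolerance = 1e-4)
  expect_equal(read_network_image(pp), img, tolerance = 1e-2)
})
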