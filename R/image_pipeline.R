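#' Read a grayscale network image
#'
#' Reads a TIFF or PNG fluorescence image as a numeric intensity matrix in
#' `[0, 1]`. Multi-channel images are averaged to grayscale. Upstream
#' acquisition processing (deconvolution, format conversion) is out of scope;
#' this pipeline starts from a 2D intensity array.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return Numeric matrix of intensities.
#' @export
read_network_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  if (length(dim(img)) != 2L) stop("image must be 2D")
  img
}

#' Write a grayscale image
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @return `path`, invisibly.
#' @export
write_network_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    png = png::writePNG(img, path),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Threshold an intensity image
#'
#' Foreground is every pixel with intensity greater than or equal to the
#' threshold.
#'
#' @param image 2D numeric matrix.
#' @param threshold intensity threshold.
#' @return Logical matrix of the same dimension.
#' @export
binarize <- function(image, threshold) {
  if (length(dim(image)) != 2L) stop("image must be a 2D matrix")
  if (length(image) == 0L) stop("empty image")
  image >= threshold
}

#' Pixel-mass census of a binary mask
#'
#' Identifies clusters as groups of foreground pixels connected through any
#' of the eight nearest neighbors (8-connectivity) and returns their pixel
#' masses. No skeletonization is applied: the pixel count of each cluster is
#' its mass.
#'
#' @param mask logical matrix (foreground = `TRUE`).
#' @return A [cluster_census()] of pixel masses, or `NULL` for an empty mask.
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' mass_census(m)$sizes  # 2: diagonal touch joins under 8-connectivity
#' @export
mass_census <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  fg <- which(mask)
  if (length(fg) == 0L) return(NULL)
  nr <- nrow(mask); nc <- ncol(mask)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg) # compact ids for foreground pixels
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L
  # undirected 8-neighborhood covered by 4 forward shifts
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  edges <- do.call(rbind, lapply(shifts, function(dd) {
    r2 <- row + dd[1L]; c2 <- col + dd[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) return(NULL)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- id[nb] > 0L
    if (!any(hit)) return(NULL)
    cbind(id[fg[ok]][hit], id[nb][hit])
  }))
  census_from_graph(length(fg), edges)
}

#' Multi-threshold analysis of one network image
#'
#' Thresholding fluorescence images is not unique: intensity is heterogeneous
#' across the organelle and out-of-plane light blurs cluster boundaries, so
#' each image is analyzed at several thresholds and the spread across
#' thresholds is propagated as the measurement uncertainty. Thresholds
#' default to fixed quantiles of the nonzero pixel intensities.
#'
#' @param image 2D intensity matrix.
#' @param thresholds absolute intensity thresholds (>= 2), or `NULL` to use
#'   `quantiles` of the nonzero intensities.
#' @param quantiles quantile levels used when `thresholds` is `NULL`.
#' @param id optional source identifier.
#' @return Object of class `image_network`: list with `id`, `thresholds`,
#'   `flagged` (thresholds outside the intensity range), `censuses` (one
#'   [cluster_census()] or `NULL` per threshold), `observables` (data.frame:
#'   per-threshold `threshold`, `N` (foreground mass), `N_g`, `order`, `N_2`,
#'   `s`), and `summary` (across-threshold mean and SD of each observable).
#' @export
threshold_ensemble <- function(image, thresholds = NULL,
                               quantiles = c(0.5, 0.6, 0.7, 0.8),
                               id = NA_character_) {
  if (length(dim(image)) != 2L) stop("image must be a 2D matrix")
  if (is.null(thresholds)) {
    nz <- image[image > 0]
    if (length(nz) == 0L) stop("image has no positive intensities")
    thresholds <- unname(quantile(nz, quantiles))
  }
  if (length(thresholds) < 2L) stop("need >= 2 thresholds")
  flagged <- thresholds < min(image) | thresholds > max(image)
  censuses <- lapply(thresholds, function(th) mass_census(binarize(image, th)))
  obs <- do.call(rbind, lapply(seq_along(thresholds), function(i) {
    cc <- censuses[[i]]
    if (is.null(cc)) {
      data.frame(threshold = thresholds[i], N = 0, N_g = 0, order = NA_real_,
                 N_2 = 0, s = NA_real_)
    } else {
      cbind(data.frame(threshold = thresholds[i]), census_observables(cc))
    }
  }))
  keep <- c("N", "N_g", "order", "N_2", "s")
  summ <- data.frame(
    observable = keep,
    mean = vapply(keep, function(k) mean(obs[[k]], na.rm = TRUE), numeric(1)),
    sd = vapply(keep, function(k) stats::sd(obs[[k]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL
  )
  structure(
    list(id = id, thresholds = thresholds, flagged = flagged,
         censuses = censuses, observables = obs, summary = summ),
    class = "image_network"
  )
}

#' @export
print.image_network <- function(x, ...) {
  cat(sprintf("<image_network> %s: %d thresholds, mass %.0f +/- %.0f px\n",
              if (is.na(x$id)) "(unnamed)" else x$id, length(x$thresholds),
              x$summary$mean[x$summary$observable == "N"],
              x$summary$sd[x$summary$observable == "N"]))
  invisible(x)
}

# one-row per-network summary used by the collection-level procedures:
# across-threshold means of N, N2, s and the order parameter
network_summary <- function(net) {
  stopifnot(inherits(net, "image_network"))
  s <- net$summary
  g <- function(k) s$mean[s$observable == k]
  data.frame(id = net$id, N = g("N"), N_g = g("N_g"), order = g("order"),
             N_2 = g("N_2"), s = g("s"))
}

#' Per-network observable table for a collection
#'
#' @param networks list of `image_network` objects.
#' @return data.frame with one row per network (`id`, `N`, `N_g`, `order`,
#'   `N_2`, `s`; across-threshold means).
#' @export
networks_table <- function(networks) {
  do.call(rbind, lapply(networks, network_summary))
}

#' Mass-ranked group CCDFs
#'
#' Ranks networks by total mass, divides them into `n_groups` groups of
#' (nearly) equal count with increasing average mass (any remainder goes to
#' the largest-mass groups), pools the cluster censuses within each group
#' (all thresholds), and returns the pooled CCDF per group. Near
#' criticality the distribution cutoff is expected to grow with the group
#' mean mass.
#'
#' @param networks list of `image_network` objects (length >= `n_groups`).
#' @param n_groups number of mass groups (default 5).
#' @return List of length `n_groups`, ordered by increasing mean mass; each
#'   element has `mean_mass`, `n_networks`, and `ccdf` (data.frame `s`, `Nc`).
#' @export
rank_group_ccdf <- function(networks, n_groups = 5L) {
  if (length(networks) < n_groups) stop("fewer networks than groups")
  tab <- networks_table(networks)
  ord <- order(tab$N)
  k <- length(networks)
  base <- k %/% n_groups
  extra <- k %% n_groups
  counts <- rep(base, n_groups) +
    c(rep(0L, n_groups - extra), rep(1L, extra)) # remainder to largest masses
  grp <- rep(seq_len(n_groups), counts)
  lapply(seq_len(n_groups), function(g) {
    members <- ord[grp == g]
    pooled <- unlist(lapply(networks[members], function(net) {
      Filter(Negate(is.null), net$censuses)
    }), recursive = FALSE)
    list(
      mean_mass = mean(tab$N[members]),
      n_networks = length(members),
      ccdf = pooled_ccdf(pooled)
    )
  })
}

#' Sliding-window finite-size scaling over a network collection
#'
#' Real networks span a range of masses; treating mass as the system size,
#' the collection is sorted by mass and a window of `n` consecutive networks
#' is slid one network at a time. Each window yields the average mass
#' \eqn{\langle N\rangle}, the average second-largest cluster
#' \eqn{\langle N_2\rangle}, the average mean cluster size
#' \eqn{\langle s\rangle}, and the fluctuation susceptibility \eqn{\chi}
#' computed from the window's order-parameter values with the window mean
#' mass as \eqn{\langle N\rangle}. Power laws fitted across windows give the
#' scaling exponents \eqn{\omega_1} (\eqn{\langle N_2\rangle} vs
#' \eqn{\langle N\rangle}), \eqn{\omega_2} (\eqn{\langle s\rangle}) and
#' \eqn{\omega_3} (\eqn{\chi}); near criticality
#' \eqn{\omega_2 \approx \omega_3 \equiv d_f/d} and
#' \eqn{\omega_1 \equiv \gamma/\nu d}.
#'
#' @param networks list of `image_network` objects.
#' @param window window size `n` (default 20; `2 <= n <= length(networks)`).
#' @return List with `windows` (data.frame `N`, `N_2`, `s`, `chi` per window)
#'   and `fits` (list of [fit_powerlaw()] results `omega1`, `omega2`,
#'   `omega3`; `NULL` with a warning when the windows give < 3 points or no
#'   dynamic range in mass).
#' @export
sliding_window_scaling <- function(networks, window = 20L) {
  n <- length(networks)
  if (window > n) stop("window larger than the collection")
  if (window < 2L) stop("window must be >= 2")
  tab <- networks_table(networks)
  ord <- order(tab$N)
  tab <- tab[ord, , drop = FALSE]
  starts <- seq_len(n - window + 1L)
  windows <- do.call(rbind, lapply(starts, function(i) {
    w <- tab[i:(i + window - 1L), , drop = FALSE]
    ok <- is.finite(w$order)
    data.frame(
      N = mean(w$N),
      N_2 = mean(w$N_2),
      s = mean(w$s, na.rm = TRUE),
      chi = if (sum(ok) >= 2L) chi(w$order[ok], mean(w$N)) else NA_real_
    )
  }))
  fit_or_null <- function(y, role) {
    ok <- is.finite(windows$N) & is.finite(y) & windows$N > 0 & y > 0
    if (sum(ok) < 3L) {
      warning("too few usable windows for ", role)
      return(NULL)
    }
    if (diff(range(windows$N[ok])) / min(windows$N[ok]) < 1e-8) {
      warning("no dynamic range in mass for ", role)
      return(NULL)
    }
    fit_powerlaw(windows$N[ok], y[ok], role = role)
  }
  list(
    windows = windows,
    fits = list(
      omega1 = fit_or_null(windows$N_2, "omega1 (<N2> ~ N)"),
      omega2 = fit_or_null(windows$s, "omega2 (<s> ~ N)"),
      omega3 = fit_or_null(windows$chi, "omega3 (chi ~ N)")
    )
  )
}
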