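#' Spatially-explicit lattice model configuration
#'
#' The spatially-explicit (SE) model places nodes on an `L x L` square
#' lattice (`N = L^2`) with periodic boundaries. Bonds are anisotropic:
#' "left/right" bonds join a node to its two nearest neighbors within the
#' same row, "side" bonds to the neighbor in the same column. Each node owns
#' one horizontal bond (to `(x+1, y)`, wrapping) and one vertical bond (to
#' `(x, y+1)`, wrapping), so every bond is controlled by exactly one node.
#'
#' @param L lattice side (>= 2 for a well-defined lattice; simulations
#'   require >= 4).
#' @param p1 probability that an update establishes a node's left and right
#'   bonds (else both are destroyed).
#' @param p2 probability that an update establishes the node's side bond.
#' @return Object of class `se_config`: list with `L`, `N`, `p1`, `p2`, and
#'   logical `L x L` matrices `h` and `v` of bond occupancies (all `FALSE`
#'   initially); `h[x, y]` is the bond from node `(x, y)` to `(x+1, y)`.
#' @export
se_config <- function(L, p1, p2) {
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) stop("p1, p2 must lie in [0, 1]")
  structure(
    list(L = L, N = L * L, p1 = p1, p2 = p2,
         h = matrix(FALSE, L, L), v = matrix(FALSE, L, L)),
    class = "se_config"
  )
}

#' Single-node update of the SE model
#'
#' Applies the anisotropic update rule at one node: with probability `p1`
#' (i.e. when `u1 < p1`) both horizontal bonds incident to the node are set
#' present, otherwise both are set absent; independently, with probability
#' `p2` the node's owned vertical bond is set present, otherwise absent. No
#' other bond changes. One joint draw governs the left and right bonds - this
#' correlation is what distinguishes the model from static anisotropic bond
#' percolation.
#'
#' @param config an [se_config()].
#' @param node integer pair `c(x, y)`, 1-indexed lattice coordinates.
#' @param u1,u2 uniform draws in `[0, 1)`; supplied explicitly so the rule is
#'   deterministic and testable ([se_simulate()] draws them internally).
#' @return The updated `se_config`.
#' @export
se_update <- function(config, node, u1, u2) {
  L <- config$L
  x <- as.integer(node[[1L]]); y <- as.integer(node[[2L]])
  if (x < 1L || x > L || y < 1L || y > L) stop("node outside lattice")
  xm1 <- if (x == 1L) L else x - 1L
  hb <- u1 < config$p1
  config$h[x, y] <- hb
  config$h[xm1, y] <- hb
  config$v[x, y] <- u2 < config$p2
  config
}

#' Edge list of an SE configuration
#'
#' Occupied bonds as an edge list over node ids `x + (y-1)*L`, with periodic
#' wrap; `wrap = FALSE` drops the bonds that cross the boundary (used when a
#' configuration is rendered to a finite image).
#'
#' @param config an [se_config()].
#' @param wrap keep boundary-crossing bonds?
#' @return Two-column integer matrix of node ids.
#' @export
se_edges <- function(config, wrap = TRUE) {
  L <- config$L
  id <- function(x, y) x + (y - 1L) * L
  hx <- which(config$h, arr.ind = TRUE)
  vx <- which(config$v, arr.ind = TRUE)
  if (!wrap) {
    if (nrow(hx)) hx <- hx[hx[, 1L] < L, , drop = FALSE]
    if (nrow(vx)) vx <- vx[vx[, 2L] < L, , drop = FALSE]
  }
  he <- if (nrow(hx)) cbind(id(hx[, 1L], hx[, 2L]),
                            id(hx[, 1L] %% L + 1L, hx[, 2L]))
        else matrix(integer(0), 0L, 2L)
  ve <- if (nrow(vx)) cbind(id(vx[, 1L], vx[, 2L]),
                            id(vx[, 1L], vx[, 2L] %% L + 1L))
        else matrix(integer(0), 0L, 2L)
  rbind(he, ve)
}

#' Cluster census of an SE configuration
#'
#' @param config an [se_config()].
#' @param wrap include periodic boundary bonds (default `TRUE`).
#' @return A [cluster_census()] of node clusters (isolated nodes are size-1
#'   clusters).
#' @export
se_census <- function(config, wrap = TRUE) {
  census_from_graph(config$N, se_edges(config, wrap = wrap))
}

#' Simulate the spatially-explicit lattice model
#'
#' Random-sequential dynamics: one sweep is `N = L^2` single-node updates at
#' uniformly chosen nodes, each applying the [se_update()] rule. Starting
#' from the empty configuration, censuses are sampled every `stride_sweeps`
#' sweeps after `burn_in_sweeps` sweeps. In the stationary state every
#' vertical bond is Bernoulli(`p2`) and every horizontal bond Bernoulli(`p1`)
#' marginally (each bond takes the outcome of whichever controlling node
#' updated last).
#'
#' @param L lattice side (>= 4).
#' @param p1,p2 bond probabilities.
#' @param burn_in_sweeps sweeps discarded before the first sample
#'   (default 200).
#' @param n_samples number of censuses.
#' @param stride_sweeps sweeps between samples (default 5).
#' @param seed integer seed for the compiled RNG, or `NULL` to draw one.
#' @param return_configs also return the sampled bond configurations (small
#'   lattices; used for independent structural checks).
#' @return Object of class `se_run`: list with `censuses` (list of
#'   [cluster_census()]), `N = L^2`, `h_frac`/`v_frac` (occupied bond
#'   fractions per sample), optionally `configs`, and the run parameters.
#' @export
se_simulate <- function(L, p1, p2, burn_in_sweeps = 200, n_samples = 10,
                        stride_sweeps = 5, seed = NULL,
                        return_configs = FALSE) {
  L <- as.integer(L)
  if (L < 4L) stop("L must be >= 4")
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1) stop("p1, p2 must lie in [0, 1]")
  if (burn_in_sweeps < 0 || n_samples < 1 || stride_sweeps < 1)
    stop("invalid sampling parameters")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  raw <- .se_simulate_cpp(L, p1, p2, burn_in_sweeps, n_samples,
                          stride_sweeps, seed, return_configs)
  out <- list(
    censuses = lapply(raw$censuses, cluster_census),
    N = L * L, L = L, p1 = p1, p2 = p2,
    h_frac = raw$h_frac, v_frac = raw$v_frac,
    burn_in_sweeps = burn_in_sweeps, stride_sweeps = stride_sweeps,
    seed = seed
  )
  if (return_configs) {
    out$configs <- lapply(raw$configs, function(cf) {
      config <- se_config(L, p1, p2)
      config$h <- cf$h
      config$v <- cf$v
      config
    })
  }
  class(out) <- "se_run"
  out
}

#' @export
print.se_run <- function(x, ...) {
  cat(sprintf(
    "<se_run> L=%d (N=%d), %d samples, p1=%g p2=%g, <Ng/N>=%.3f\n",
    x$L, x$N, length(x$censuses), x$p1, x$p2,
    mean(vapply(x$censuses, function(cc) cc$N_g / cc$N, numeric(1)))))
  invisible(x)
}
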