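#' Cluster census
#'
#' A cluster census is the multiset of cluster sizes (or pixel masses) of one
#' network configuration. It is the common currency of the package: both
#' simulators, the image pipeline and the synthetic generators all reduce to
#' censuses, and every percolation observable is a function of a census.
#'
#' @param sizes positive integer vector of cluster sizes.
#' @return An object of class `cluster_census`: a list with elements `sizes`
#'   (sizes sorted in decreasing order), `N` (total mass, the sum of sizes),
#'   `N_g` (largest cluster), and `N_2` (second-largest cluster, 0 if the
#'   census holds a single cluster).
#' @examples
#' cc <- cluster_census(c(5, 2, 1, 1))
#' cc$N_g  # 5
#' cc$N_2  # 2
#' @export
cluster_census <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L) stop("empty census")
  if (any(sizes < 1L)) stop("cluster sizes must be positive integers")
  sizes <- sort(sizes, decreasing = TRUE)
  structure(
    list(
      sizes = sizes,
      N = sum(sizes),
      N_g = sizes[[1L]],
      N_2 = if (length(sizes) >= 2L) sizes[[2L]] else 0L
    ),
    class = "cluster_census"
  )
}

#' @export
print.cluster_census <- function(x, ...) {
  cat("<cluster_census> ", length(x$sizes), " clusters, total mass N = ",
      x$N, ", N_g = ", x$N_g, ", N_2 = ", x$N_2, "\n", sep = "")
  invisible(x)
}

as_census <- function(x) {
  if (inherits(x, "cluster_census")) x else cluster_census(x)
}

#' Connected-component census of a graph
#'
#' Labels connected components with a union-find (disjoint-set) structure and
#' returns their sizes as a [cluster_census()]. Isolated nodes count as
#' clusters of size 1.
#'
#' @param n_nodes number of nodes, labelled `1:n_nodes`.
#' @param edges two-column integer matrix of undirected links (may have zero
#'   rows). Endpoints outside `1:n_nodes` are an error.
#' @return A [cluster_census()].
#' @examples
#' census_from_graph(5, rbind(c(1, 2), c(2, 3)))$sizes  # 3 1 1
#' @export
census_from_graph <- function(n_nodes, edges = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop("n_nodes must be >= 1")
  parent <- seq_len(n_nodes)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {
      nxt <- parent[x]
      parent[x] <<- root
      x <- nxt
    }
    root
  }
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(is.na(edges)) || any(edges < 1L) || any(edges > n_nodes))
      stop("edge endpoints must reference nodes in 1:n_nodes")
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges[i, 1L])
      rb <- find(edges[i, 2L])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n_nodes), find, integer(1))
  cluster_census(tabulate(roots, nbins = n_nodes)[unique(roots)])
}

#' Mean cluster size (susceptibility proxy)
#'
#' The second-moment-weighted mean cluster size
#' \deqn{\langle s\rangle = \sum' s^2 n_s \big/ \sum' s\, n_s,}
#' where the primed sums exclude the largest cluster (exactly one instance is
#' dropped when several clusters tie for largest). This quantity peaks at the
#' percolation transition and serves as the susceptibility proxy throughout
#' the finite-size scaling analysis. A census holding a single cluster returns
#' 0 by convention so that sweep curves are total functions.
#'
#' @param census a [cluster_census()] or an integer vector of sizes.
#' @return Numeric scalar.
#' @examples
#' mean_cluster_size(c(5, 2, 1, 1))  # 1.5
#' @export
mean_cluster_size <- function(census) {
  census <- as_census(census)
  rest <- census$sizes[-1L] # sizes sorted decreasing: drop one largest
  if (length(rest) == 0L) return(0)
  sum(as.numeric(rest)^2) / sum(as.numeric(rest))
}

#' Complementary cumulative cluster-size distribution
#'
#' The CCDF of the normalized cluster-number distribution,
#' \deqn{N_c(s) = \sum'_{s' \ge s} n_s(s'),}
#' with \eqn{n_s = N_s / N} (clusters of size s per unit total mass) and the
#' primed sum excluding the largest ("giant") cluster of the configuration.
#' By construction \eqn{N_c} is nonincreasing and
#' \eqn{N_c(1) = (\text{cluster count} - 1)/N}.
#'
#' @param census a [cluster_census()] or integer vector of sizes.
#' @return A data.frame with columns `s` (the distinct non-giant cluster
#'   sizes, increasing) and `Nc`. For a single-cluster census a zero-row
#'   data.frame is returned (the CCDF is identically 0).
#' @examples
#' ccdf(c(10, 2, 1, 1))  # Nc(1) = 3/14, Nc(2) = 1/14
#' @export
ccdf <- function(census) {
  census <- as_census(census)
  rest <- census$sizes[-1L]
  if (length(rest) == 0L)
    return(data.frame(s = integer(0), Nc = numeric(0)))
  s <- sort(unique(rest))
  counts <- vapply(s, function(v) sum(rest >= v), numeric(1))
  data.frame(s = s, Nc = counts / census$N)
}

#' Pooled CCDF over an ensemble of censuses
#'
#' Pools the non-giant cluster sizes of several configurations (dropping one
#' largest cluster per configuration) and evaluates the ensemble CCDF,
#' normalized by the summed total mass.
#'
#' @param censuses list of censuses (or integer size vectors).
#' @return data.frame with columns `s` and `Nc`.
#' @export
pooled_ccdf <- function(censuses) {
  parts <- lapply(censuses, function(x) as_census(x)$sizes[-1L])
  total_mass <- sum(vapply(censuses, function(x) as_census(x)$N, numeric(1)))
  rest <- unlist(parts)
  if (length(rest) == 0L)
    return(data.frame(s = integer(0), Nc = numeric(0)))
  s <- sort(unique(rest))
  counts <- vapply(s, function(v) sum(rest >= v), numeric(1))
  data.frame(s = s, Nc = counts / total_mass)
}

#' Order-parameter fluctuation susceptibility
#'
#' \deqn{\chi = \langle N\rangle\left[\langle (N_g/N)^2\rangle -
#'   \langle N_g/N\rangle^2\right],}
#' i.e. the mean system size times the population variance of the order
#' parameter \eqn{N_g/N} across configurations. The population (biased)
#' variance is used; the number of samples is the caller's to report.
#'
#' @param order_samples numeric vector of \eqn{N_g/N} values (length >= 2).
#' @param N_mean mean total mass \eqn{\langle N\rangle} of the ensemble.
#' @return Nonnegative numeric scalar.
#' @examples
#' chi(c(0, 1), 4)  # 4 * (0.5 - 0.25) = 1
#' @export
chi <- function(order_samples, N_mean) {
  if (length(order_samples) < 2L) stop("chi needs at least 2 samples")
  m <- mean(order_samples)
  N_mean * (mean(order_samples^2) - m^2)
}

#' Percolation observables of one census
#'
#' @param census a [cluster_census()] or integer vector of sizes.
#' @return A one-row data.frame with columns `N`, `N_g`, `order` (=N_g/N),
#'   `N_2`, and `s` (mean cluster size per [mean_cluster_size()]).
#' @export
census_observables <- function(census) {
  census <- as_census(census)
  data.frame(
    N = census$N,
    N_g = census$N_g,
    order = census$N_g / census$N,
    N_2 = census$N_2,
    s = mean_cluster_size(census)
  )
}

#' Summarize an ensemble of censuses
#'
#' Ensemble means of the percolation observables plus the fluctuation
#' susceptibility [chi()] computed from the ensemble's order-parameter values.
#'
#' @param censuses list of censuses (or integer size vectors).
#' @return One-row data.frame with columns `n_samples`, `N`, `order`, `N_2`,
#'   `s`, `chi`.
#' @export
summarize_censuses <- function(censuses) {
  obs <- do.call(rbind, lapply(censuses, census_observables))
  data.frame(
    n_samples = nrow(obs),
    N = mean(obs$N),
    order = mean(obs$order),
    N_2 = mean(obs$N_2),
    s = mean(obs$s),
    chi = if (nrow(obs) >= 2L) chi(obs$order, mean(obs$N)) else NA_real_
  )
}

#' Read and write census ensembles as CSV
#'
#' The on-disk schema is long-form with columns `sample_index`,
#' `cluster_size`, `count`, one row per distinct size per sample.
#'
#' @param censuses list of censuses (or integer size vectors).
#' @param path file path.
#' @return `write_censuses` returns `path` invisibly; `read_censuses` returns
#'   a list of [cluster_census()] objects.
#' @export
write_censuses <- function(censuses, path) {
  rows <- lapply(seq_along(censuses), function(i) {
    sizes <- as_census(censuses[[i]])$sizes
    tab <- table(sizes)
    data.frame(
      sample_index = i,
      cluster_size = as.integer(names(tab)),
      count = as.integer(tab)
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_censuses
#' @export
read_censuses <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("sample_index", "cluster_size", "count") %in% names(df)))
  lapply(split(df, df$sample_index), function(d) {
    cluster_census(rep(d$cluster_size, d$count))
  })
}
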