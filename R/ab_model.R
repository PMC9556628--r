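#' Fission-fusion reaction rates for the agent-based model
#'
#' The agent-based (AB) model evolves through two reversible mass-action
#' reactions over node species \eqn{X_k} (junctions of degree k):
#' tip-to-tip, \eqn{2X_1 \rightleftharpoons X_2}, with association rate
#' \eqn{a_1} and dissociation rate \eqn{b_1}; and tip-to-side,
#' \eqn{X_1 + X_2 \rightleftharpoons X_3}, with rates \eqn{a_2}, \eqn{b_2}.
#' The dimensionless relative rates \eqn{c_i = a_i/b_i} are the natural
#' control parameters; only one type of fission is observed experimentally,
#' so by default \eqn{b_2 = (3/2) b_1}.
#'
#' @param c1,c2 relative rates \eqn{a_i/b_i}; give these (the usual
#'   parameterization) or `a1`/`a2` directly.
#' @param b1 tip-to-tip dissociation rate (per degree-2 node); sets the time
#'   unit.
#' @param b2 tip-to-side dissociation rate (per degree-3 node); defaults to
#'   `1.5 * b1`.
#' @param a1,a2 association rates; computed from `c1`/`c2` when omitted.
#' @return Object of class `ab_rates` with fields `a1`, `b1`, `a2`, `b2`,
#'   `c1`, `c2` kept mutually consistent.
#' @examples
#' r <- ab_rates(c1 = 0.01, c2 = 2e-4)
#' r$a2  # c2 * b2 = 2e-4 * 1.5
#' @export
ab_rates <- function(c1 = NULL, c2 = NULL, b1 = 1, b2 = 1.5 * b1,
                     a1 = NULL, a2 = NULL) {
  if (is.null(a1)) {
    if (is.null(c1)) stop("give either c1 or a1")
    a1 <- c1 * b1
  }
  if (is.null(a2)) {
    if (is.null(c2)) stop("give either c2 or a2")
    a2 <- c2 * b2
  }
  rates <- c(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  structure(
    list(a1 = a1, b1 = b1, a2 = a2, b2 = b2,
         c1 = if (b1 > 0) a1 / b1 else Inf,
         c2 = if (b2 > 0) a2 / b2 else Inf),
    class = "ab_rates"
  )
}

#' @export
print.ab_rates <- function(x, ...) {
  cat(sprintf(
    "<ab_rates> a1=%g b1=%g a2=%g b2=%g (c1=%g, c2=%g)\n",
    x$a1, x$b1, x$a2, x$b2, x$c1, x$c2))
  invisible(x)
}

#' Agent-based model state
#'
#' A state of the AB model: `Ne` indivisible edge-units (minimal mitochondrial
#' fragments), each with two endpoints gathered into junction nodes of degree
#' 1 (free tip), 2 (bulk site) or 3 (branch point). The initial condition is
#' fully fragmented: every unit isolated, all nodes degree 1.
#'
#' @param Ne number of edge-units (fixed for the lifetime of a simulation).
#' @return Object of class `ab_state`: a list with `Ne` and `units`, an
#'   `Ne x 2` integer matrix giving the node id of each unit endpoint.
#' @export
ab_state <- function(Ne) {
  Ne <- as.integer(Ne)
  if (Ne < 2L) stop("Ne must be >= 2")
  structure(
    list(Ne = Ne, units = matrix(seq_len(2L * Ne), ncol = 2L, byrow = TRUE)),
    class = "ab_state"
  )
}

ab_degrees <- function(state) {
  tabulate(tabulate(state$units, nbins = max(state$units)), nbins = 3L)
}

ab_degree_of <- function(state) {
  deg <- tabulate(state$units, nbins = max(state$units))
  deg
}

# count of isolated units (both endpoints degree 1)
ab_n_isolated <- function(state) {
  deg <- ab_degree_of(state)
  sum(deg[state$units[, 1L]] == 1L & deg[state$units[, 2L]] == 1L &
        state$units[, 1L] != state$units[, 2L])
}

#' Validate an AB state
#'
#' Checks the structural invariants: every node degree in {1,2,3} and
#' endpoint conservation \eqn{\sum_k k X_k = 2 N_e}.
#' @param state an [ab_state()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
ab_validate <- function(state) {
  deg <- ab_degree_of(state)
  deg <- deg[deg > 0L]
  if (any(deg > 3L)) stop("node degree above 3")
  X <- ab_degrees(state)
  if (sum(seq_len(3L) * X) != 2L * state$Ne)
    stop("endpoint conservation violated")
  invisible(TRUE)
}

#' Reaction-channel propensities of the AB model
#'
#' The four channel rates under mass-action kinetics:
#' tip-tip fusion `a1 * (admissible degree-1 pairs)`, tip-tip fission
#' `b1 * X2`, tip-side fusion `a2 * X1 * X2`, tip-side fission `b2 * X3`.
#' The two tips of one isolated unit are not an admissible fusion pair (a
#' single unit cannot close on itself); tips elsewhere in the same cluster
#' are admissible, so rings can form.
#'
#' @param state an [ab_state()].
#' @param rates an [ab_rates()].
#' @return Named numeric vector
#'   `c(tt_fusion, tt_fission, ts_fusion, ts_fission)`; all entries >= 0 and
#'   a channel is 0 exactly when no admissible reactant exists.
#' @examples
#' s <- ab_state(2) # two isolated units: X1 = 4
#' ab_propensities(s, ab_rates(a1 = 1, a2 = 0, b1 = 0, b2 = 0))
#' # tt_fusion = 1 * (choose(4,2) - 2) = 4
#' @export
ab_propensities <- function(state, rates) {
  X <- ab_degrees(state)
  n_iso <- ab_n_isolated(state)
  pairs <- X[1L] * (X[1L] - 1) / 2 - n_iso
  c(
    tt_fusion = rates$a1 * max(pairs, 0),
    tt_fission = rates$b1 * X[2L],
    ts_fusion = rates$a2 * X[1L] * X[2L],
    ts_fission = rates$b2 * X[3L]
  )
}

#' One Gillespie event of the AB model
#'
#' Draws an exponential waiting time from the total propensity, picks a
#' channel with probability proportional to its propensity, and applies it:
#' tip-tip fusion merges two degree-1 nodes into a degree-2 node; tip-tip
#' fission splits a degree-2 node; tip-side fusion merges a degree-1 and a
#' degree-2 node into a degree-3 node; tip-side fission detaches one of the
#' three incident unit endpoints (chosen uniformly) from a degree-3 node.
#' Uses R's RNG, so runs are reproducible under [set.seed()].
#'
#' This reference implementation is O(Ne) per event and intended for small
#' systems and validation; [ab_simulate()] runs the same dynamics in compiled
#' code.
#'
#' @param state an [ab_state()].
#' @param rates an [ab_rates()].
#' @return List with elements `state` (updated) and `dt` (elapsed time).
#'   Errors with message "absorbing state" if every propensity is 0.
#' @export
ab_step <- function(state, rates) {
  prop <- ab_propensities(state, rates)
  total <- sum(prop)
  if (total <= 0) stop("absorbing state: all propensities are zero")
  dt <- -log(runif(1)) / total
  channel <- sample.int(4L, 1L, prob = prop)
  deg <- ab_degree_of(state)
  units <- state$units
  nodes_of_deg <- function(k) which(deg == k)
  fresh <- max(units) + 1L
  if (channel == 1L) { # tip-tip fusion
    tips <- nodes_of_deg(1L)
    repeat {
      pair <- sample(tips, 2L)
      same_unit <- any(units[, 1L] %in% pair & units[, 2L] %in% pair)
      if (!same_unit) break
    }
    units[units == pair[2L]] <- pair[1L]
  } else if (channel == 2L) { # tip-tip fission
    nd <- resample(nodes_of_deg(2L), 1L)
    idx <- which(units == nd)
    units[idx[2L]] <- fresh
  } else if (channel == 3L) { # tip-side fusion
    tip <- resample(nodes_of_deg(1L), 1L)
    bulk <- resample(nodes_of_deg(2L), 1L)
    units[units == tip] <- bulk
  } else { # tip-side fission
    nd <- resample(nodes_of_deg(3L), 1L)
    idx <- which(units == nd)
    units[resample(idx, 1L)] <- fresh
  }
  state$units <- units
  list(state = state, dt = dt)
}

# sample() that treats a length-1 vector as a set, not 1:n
resample <- function(x, n) x[sample.int(length(x), n)]

#' Cluster census of an AB state
#'
#' Clusters are maximal sets of units connected through shared junction
#' nodes; sizes are counted in units.
#' @param state an [ab_state()].
#' @return A [cluster_census()].
#' @export
ab_census <- function(state) {
  # connect units that share a node: for each node, link its incident units
  units <- state$units
  node_units <- split(rep(seq_len(nrow(units)), 2L), as.vector(units))
  edges <- do.call(rbind, lapply(node_units, function(u) {
    u <- unique(u)
    if (length(u) < 2L) return(NULL)
    cbind(u[1L], u[-1L])
  }))
  census_from_graph(state$Ne, edges)
}

#' Simulate the agent-based fission-fusion model
#'
#' Continuous-time Gillespie simulation from the fully fragmented initial
#' condition, sampling cluster censuses every `stride` events after `burn_in`
#' events. Event-count based sampling is used because observables are
#' stationary-state properties; elapsed model time is returned as metadata.
#' If the system reaches an absorbing state (all propensities zero, e.g. all
#' rates 0), the frozen state fills the remaining samples.
#'
#' @param Ne number of edge-units (>= 2).
#' @param rates an [ab_rates()].
#' @param burn_in events discarded before the first sample
#'   (default `50 * Ne`).
#' @param n_samples number of censuses to return.
#' @param stride events between samples (default `5 * Ne`).
#' @param seed integer seed (compiled engine) or `NULL` to draw one from R's
#'   RNG.
#' @param engine `"cpp"` (default, compiled) or `"r"` (the [ab_step()]
#'   reference loop; small systems only).
#' @return Object of class `ab_run`: list with `censuses` (list of
#'   [cluster_census()]), `Xk` (`n_samples x 3` matrix of degree counts),
#'   `N = Ne`, `time` (elapsed model time), `units` (final unit graph,
#'   endpoint node ids), `absorbed`, and the run parameters.
#' @export
ab_simulate <- function(Ne, rates, burn_in = 50 * Ne, n_samples = 10,
                        stride = 5 * Ne, seed = NULL,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  Ne <- as.integer(Ne)
  if (Ne < 2L) stop("Ne must be >= 2")
  if (stride < 1 || burn_in < 0 || n_samples < 1)
    stop("invalid sampling parameters")
  if (!inherits(rates, "ab_rates")) stop("rates must be an ab_rates object")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  if (engine == "cpp") {
    raw <- .ab_simulate_cpp(Ne, rates$a1, rates$b1, rates$a2, rates$b2,
                            burn_in, n_samples, stride, seed)
    censuses <- lapply(raw$censuses, cluster_census)
    out <- list(censuses = censuses, Xk = raw$Xk, N = Ne, time = raw$time,
                units = raw$units, absorbed = raw$absorbed,
                rates = rates, burn_in = burn_in, stride = stride,
                seed = seed)
  } else {
    set.seed(seed)
    state <- ab_state(Ne)
    t <- 0
    absorbed <- FALSE
    advance <- function(n) {
      for (i in seq_len(n)) {
        if (absorbed) return(invisible(NULL))
        step <- tryCatch(ab_step(state, rates), error = function(e) NULL)
        if (is.null(step)) {
          absorbed <<- TRUE
          return(invisible(NULL))
        }
        state <<- step$state
        t <<- t + step$dt
      }
    }
    censuses <- vector("list", n_samples)
    Xk <- matrix(0L, n_samples, 3L)
    advance(burn_in)
    for (i in seq_len(n_samples)) {
      if (i > 1L) advance(stride)
      censuses[[i]] <- ab_census(state)
      Xk[i, ] <- ab_degrees(state)
    }
    out <- list(censuses = censuses, Xk = Xk, N = Ne, time = t,
                units = state$units, absorbed = absorbed, rates = rates,
                burn_in = burn_in, stride = stride, seed = seed)
  }
  class(out) <- "ab_run"
  out
}

#' @export
print.ab_run <- function(x, ...) {
  cat(sprintf(
    "<ab_run> Ne=%d, %d samples, c1=%g c2=%g, <Ng/N>=%.3f\n",
    x$N, length(x$censuses), x$rates$c1, x$rates$c2,
    mean(vapply(x$censuses, function(cc) cc$N_g / cc$N, numeric(1)))))
  invisible(x)
}
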