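test_that("ab_rates derives consistent relative rates", {
  r <- ab_rates(c1 = 0.01, c2 = 2e-4)
  expect_equal(r$a1, 0.01)
  expect_equal(r$b2, 1.5) # b2 = (3/2) b1 by default
  expect_equal(r$a2, 2e-4 * 1.5)
  expect_equal(r$c2, 2e-4)
  r2 <- ab_rates(a1 = 0.4, a2 = 0.2, b1 = 2)
  expect_equal(r2$c1, 0.2)
  expect_error(ab_rates(c1 = -1, c2 = 0), "rates")
  expect_error(ab_rates(c2 = 1), "c1 or a1")
})

test_that("channel propensities follow the admissible-pair counts", {
  # two isolated units: C(4,2)=6 tip pairs minus the 2 same-unit pairs
  s <- ab_state(2)
  p <- ab_propensities(s, ab_rates(a1 = 1, a2 = 0, b1 = 0, b2 = 0))
  expect_equal(unname(p), c(4, 0, 0, 0))
  # open 6-chain: X1=2, X2=5, X3=0
  p2 <- ab_propensities(chain_state(6), ab_rates(a1 = 0, a2 = 0.5, b1 = 2))
  expect_equal(p2[["ts_fusion"]], 5)   # a2 * X1 * X2 = 0.5 * 10
  expect_equal(p2[["tt_fission"]], 10) # b1 * X2
  expect_equal(p2[["ts_fission"]], 0)  # no degree-3 nodes
  expect_true(all(p2 >= 0))
})

test_that("ab_step applies single open channels correctly", {
  set.seed(1)
  # only tip-tip fusion possible: X1 drops by 2, X2 rises by 1
  s <- ab_state(3)
  r <- ab_rates(a1 = 1, a2 = 0, b1 = 0, b2 = 0)
  out <- ab_step(s, r)
  X <- tabulate(tabulate(out$state$units, nbins = max(out$state$units)), 3)
  expect_equal(X, c(4L, 1L, 0L))
  expect_gt(out$dt, 0)
  # 2-chain with only fission open: yields two isolated units
  ch <- chain_state(2)
  rf <- ab_rates(a1 = 0, a2 = 0, b1 = 1)
  out2 <- ab_step(ch, rf)
  expect_equal(ab_census(out2$state)$sizes, c(1L, 1L))
  # absorbing state signalled when no channel is open
  expect_error(ab_step(ab_state(2), ab_rates(a1 = 0, a2 = 0, b1 = 1)),
               "absorbing")
})

test_that("events conserve endpoints and respect the degree bound", {
  set.seed(42)
  state <- ab_state(12)
  r <- ab_rates(c1 = 0.5, c2 = 0.3, b1 = 1)
  for (i in 1:300) {
    state <- ab_step(state, r)$state
    expect_silent(ab_validate(state)) # sum k*Xk = 2 Ne, degrees <= 3
  }
  expect_true(all(state_degrees(state) <= 3))
})

test_that("frozen dynamics return all-singleton censuses", {
  run <- ab_simulate(20, ab_rates(a1 = 0, a2 = 0, b1 = 0, b2 = 0),
                     n_samples = 3, seed = 9)
  expect_true(run$absorbed)
  for (cc in run$censuses) expect_equal(cc$sizes, rep(1L, 20))
})

test_that("Ne=2 occupancies match the exact three-state stationary law", {
  # states: 2 singletons A (X=(4,0,0)), open chain B (2,1,0), ring C (0,2,0)
  # transition rates: A->B 4 a1, B->A b1, B->C a1, C->B 2 b1; detailed
  # balance gives continuous-time pi proportional to (1, 4 c1, 2 c1^2).
  # Event-stride sampling observes the embedded jump chain, whose law
  # weights each state by its total exit rate.
  a1 <- 1; b1 <- 1
  run <- ab_simulate(2, ab_rates(a1 = a1, a2 = 0, b1 = b1),
                     burn_in = 200, n_samples = 4000, stride = 3, seed = 11)
  lab <- apply(run$Xk, 1, function(x) paste(x, collapse = ","))
  freq <- table(factor(lab, levels = c("4,0,0", "2,1,0", "0,2,0")))
  c1 <- a1 / b1
  pi_time <- c(1, 4 * c1, 2 * c1^2)
  exit <- c(4 * a1, b1 + a1, 2 * b1)
  pi_jump <- pi_time * exit
  pi_jump <- pi_jump / sum(pi_jump)
  expect_lt(max(abs(freq / sum(freq) - pi_jump)), 0.05)
})

test_that("compiled censuses agree with a BFS labeling of the unit graph", {
  for (seed in 1:5) {
    run <- ab_simulate(40, ab_rates(c1 = 0.3, c2 = 0.05, b1 = 1),
                       burn_in = 500, n_samples = 3, stride = 100,
                       seed = seed)
    # the returned unit graph is the state of the last census
    units <- run$units
    edges <- NULL
    node_units <- split(rep(seq_len(nrow(units)), 2), as.vector(units))
    for (u in node_units) {
      u <- unique(u)
      if (length(u) >= 2) edges <- rbind(edges, cbind(u[1], u[-1]))
    }
    expect_equal(run$censuses[[3]]$sizes, bfs_census(40, edges))
    expect_true(all(tabulate(units) <= 3))
    # endpoint conservation at every sample
    expect_true(all(run$Xk %*% c(1, 2, 3) == 2 * 40))
  }
})

test_that("reference R engine and compiled engine sample the same law", {
  # small system: compare stationary fragment counts loosely
  rr <- ab_simulate(30, ab_rates(c1 = 0.2, c2 = 0.02, b1 = 1),
                    burn_in = 800, n_samples = 25, stride = 60,
                    seed = 3, engine = "r")
  rc <- ab_simulate(30, ab_rates(c1 = 0.2, c2 = 0.02, b1 = 1),
                    burn_in = 800, n_samples = 25, stride = 60, seed = 3)
  m_r <- mean(vapply(rr$censuses, function(x) length(x$sizes), numeric(1)))
  m_c <- mean(vapply(rc$censuses, function(x) length(x$sizes), numeric(1)))
  expect_lt(abs(m_r - m_c), 4)
  for (cc in rr$censuses) expect_equal(cc$N, 30L)
})

test_that("ab_simulate is reproducible and validates parameters", {
  a <- ab_simulate(50, ab_rates(c1 = 0.1, c2 = 0.01), n_samples = 3,
                   seed = 77)
  b <- ab_simulate(50, ab_rates(c1 = 0.1, c2 = 0.01), n_samples = 3,
                   seed = 77)
  expect_identical(lapply(a$censuses, `[[`, "sizes"),
                   lapply(b$censuses, `[[`, "sizes"))
  expect_error(ab_simulate(1, ab_rates(c1 = 1, c2 = 1)), "Ne")
  expect_error(ab_simulate(10, ab_rates(c1 = 1, c2 = 1), stride = 0),
               "sampling")
})
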