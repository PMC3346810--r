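toggle <- rbind(c(0L, -1L), c(-1L, 0L))
osc <- rbind(c(-1L, 1L), c(1L, -1L))
# deletion mutant of the toggle with a penalized self-flip at (1,0)
toggle_mut <- rbind(c(0L, 0L), c(-1L, 0L))

test_that("transition probabilities are flip counts normalized by L x n (hand-traced cases)", {
  g <- attractor_graph(toggle)
  es <- ergodic_sets(g)[[1]]
  P <- transition_matrix(es, g, lambda = 1)
  expect_equal(P["0", "1"], 0.5)
  expect_equal(P["0", "2"], 0.5)
  expect_equal(P["1", "0"], 1)
  expect_equal(P["2", "0"], 1)

  # the oscillator's length-2 cycle: its 4 flips split evenly
  g2 <- attractor_graph(osc)
  es2 <- ergodic_sets(g2)[[1]]
  P2 <- transition_matrix(es2, g2, lambda = 1)
  expect_equal(P2["1-2", "0"], 0.5)
  expect_equal(P2["1-2", "3"], 0.5)
  expect_equal(P2["0", "1-2"], 1)
  expect_equal(P2["3", "1-2"], 1)
})

test_that("lambda = 1 with the penalty enabled reproduces the plain chain", {
  for (s in 1:15) {
    A <- random_tbn(5, 0.5, seed = 500 + s)
    g <- attractor_graph(A)
    for (es in ergodic_sets(g)) {
      expect_equal(transition_matrix(es, g, lambda = 1, use_penalty = TRUE),
                   transition_matrix(es, g, use_penalty = FALSE))
    }
  }
})

test_that("the penalty reweights penalized flips by lambda (hand-derived mutant chain)", {
  g <- attractor_graph(toggle_mut)
  es <- ergodic_sets(g, lambda = 0.5)[[1]]
  P <- transition_matrix(es, g, lambda = 0.5, use_penalty = TRUE)
  # at (1,0) the flip of gene 2 is penalized (field -1) and is a self
  # transition; weights (1, 1/2) normalize to (2/3, 1/3)
  expect_equal(P["1", "0"], 2 / 3)
  expect_equal(P["1", "1"], 1 / 3)
  expect_equal(unname(es$stationary),
               c(8 / 21, 9 / 21, 4 / 21), tolerance = 1e-12)
})

test_that("returned matrices are row-stochastic and stationary vectors solve pi P = pi", {
  for (s in 1:40) {
    A <- random_tbn(5, 0.5, seed = 700 + s)
    g <- attractor_graph(A)
    for (lam in c(0.5, 1)) {
      for (es in ergodic_sets(g, lambda = lam)) {
        P <- transition_matrix(es, g, lambda = lam)
        expect_true(all(abs(rowSums(P) - 1) < 1e-12))
        pi <- stationary_distribution(P)
        expect_true(all(pi >= 0))
        expect_equal(sum(pi), 1, tolerance = 1e-10)
        expect_lt(max(abs(pi %*% P - pi)), 1e-9)
        expect_equal(unname(es$stationary), unname(pi))
      }
    }
  }
})

test_that("stationary distributions match hand-solved balance equations", {
  expect_equal(unname(ergodic_sets(toggle)[[1]]$stationary),
               c(0.5, 0.25, 0.25), tolerance = 1e-12)
  expect_equal(unname(ergodic_sets(osc)[[1]]$stationary),
               c(0.25, 0.5, 0.25), tolerance = 1e-12)
  # one-member ES
  expect_equal(unname(ergodic_sets(matrix(1L, 2, 2))[[1]]$stationary), 1)
  # plain chain of the toggle mutant: (1/3, 1/2, 1/6) on ((0,0),(1,0),(0,1))
  expect_equal(unname(ergodic_sets(toggle_mut, lambda = 1)[[1]]$stationary),
               c(1 / 3, 1 / 2, 1 / 6), tolerance = 1e-12)
})

test_that("stationary solve rejects non-stochastic input", {
  expect_error(stationary_distribution(matrix(c(0.5, 0.2, 0.5, 0.5), 2, 2)),
               class = "tbn_invalid_input")
  expect_error(stationary_distribution(matrix(-1, 1, 1)),
               class = "tbn_invalid_input")
})

test_that("the penalized distribution converges to the plain one as lambda approaches 1", {
  g <- attractor_graph(toggle_mut)
  plain <- ergodic_sets(g, lambda = 1, use_penalty = FALSE)[[1]]$stationary
  lams <- c(0.2, 0.4, 0.6, 0.8, 1)
  gaps <- vapply(lams, function(lam)
    max(abs(ergodic_sets(g, lambda = lam)[[1]]$stationary - plain)),
    numeric(1))
  expect_equal(gaps[length(gaps)], 0, tolerance = 1e-12)
  expect_true(all(diff(gaps) <= 1e-12))
  # and on a random fixture with at least one penalized ES flip
  A <- random_tbn(5, 0.5, seed = 811)
  g2 <- attractor_graph(A)
  plain2 <- ergodic_sets(g2, lambda = 1, use_penalty = FALSE)[[1]]$stationary
  gaps2 <- vapply(lams, function(lam)
    max(abs(ergodic_sets(g2, lambda = lam)[[1]]$stationary - plain2)),
    numeric(1))
  expect_true(all(diff(gaps2) <= 1e-12))
})

test_that("mean attractor length averages member lengths uniformly", {
  expect_equal(mean_attractor_length(ergodic_sets(toggle)[[1]]), 1)
  expect_equal(mean_attractor_length(ergodic_sets(osc)[[1]]), 4 / 3)
})

test_that("Monte-Carlo simulation of the flip process reproduces the stationary occupancy", {
  # simulate the jump chain at the flip level: pick a cycle state uniformly,
  # a gene uniformly, accept flips with probability proportional to their
  # penalty weight; compare attractor occupancy to pi with batch-mean SEs
  simulate_occupancy <- function(A, lambda, use_penalty, steps) {
    g <- attractor_graph(A)
    es <- ergodic_sets(g, lambda = lambda, use_penalty = use_penalty)[[1]]
    tr <- g$transitions
    # per-member flip tables
    flips <- lapply(es$attractor_indices, function(a) {
      rows <- tr[tr$from == a, ]
      w <- ifelse(use_penalty & rows$penalized, lambda, 1)
      list(to = rows$to, w = w / sum(w))
    })
    cur <- 1L
    visits <- integer(length(flips))
    occ <- matrix(0, nrow = 50, ncol = length(flips))
    per_batch <- steps / 50
    for (b in 1:50) {
      for (k in seq_len(per_batch)) {
        f <- flips[[cur]]
        pick <- f$to[sample.int(length(f$to), 1, prob = f$w)]
        cur <- match(pick, es$attractor_indices)
        occ[b, cur] <- occ[b, cur] + 1
      }
    }
    occ <- occ / per_batch
    list(mean = colMeans(occ), se = apply(occ, 2, sd) / sqrt(50),
         pi = unname(es$stationary))
  }
  set.seed(123)
  for (cfg in list(list(A = toggle, lambda = 1, pen = FALSE),
                   list(A = osc, lambda = 1, pen = FALSE),
                   list(A = toggle_mut, lambda = 0.5, pen = TRUE))) {
    r <- simulate_occupancy(cfg$A, cfg$lambda, cfg$pen, steps = 50000)
    expect_true(all(abs(r$mean - r$pi) <= 3 * pmax(r$se, 1e-4)))
  }
})
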