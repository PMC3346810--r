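test_that("the threshold update follows the sign of the field and retains on ties", {
  toggle <- rbind(c(0L, -1L), c(-1L, 0L))
  # field (0, -1): gene 1 retains, gene 2 switches off
  expect_equal(tbn_update(toggle, c(1, 0)), c(1L, 0L))
  # zero matrix: every field is 0, every state is retained
  zeros3 <- matrix(0L, 3, 3)
  for (s in 0:7) {
    x <- decode_state(s, 3)
    expect_equal(tbn_update(zeros3, x), x)
  }
  osc <- rbind(c(-1L, 1L), c(1L, -1L))
  expect_equal(tbn_update(osc, c(1, 0)), c(0L, 1L))
  # deterministic: repeated calls agree bitwise
  A <- random_tbn(6, 0.5, seed = 5)
  x <- decode_state(37, 6)
  expect_identical(tbn_update(A, x), tbn_update(A, x))
})

test_that("invalid states and matrices are rejected with typed errors", {
  toggle <- rbind(c(0L, -1L), c(-1L, 0L))
  expect_error(tbn_update(toggle, c(1, 0, 1)), class = "tbn_invalid_input")
  expect_error(tbn_update(toggle, c(1, 2)), class = "tbn_invalid_input")
  expect_error(tbn_network(rbind(c(0, 2), c(0, 0))), class = "tbn_invalid_input")
  expect_error(tbn_network(matrix(0L, 2, 3)), class = "tbn_invalid_input")
  expect_error(enumerate_attractors(matrix(0L, 30, 30)),
               class = "tbn_capacity_error")
})

test_that("find_attractor returns the canonical cycle and transient length", {
  toggle <- rbind(c(0L, -1L), c(-1L, 0L))
  r <- find_attractor(toggle, c(1, 1))
  expect_equal(r$attractor$codes, 0L)
  expect_equal(r$attractor$kind, "fixed_point")
  expect_equal(r$transient, 1L)

  osc <- rbind(c(-1L, 1L), c(1L, -1L))
  r <- find_attractor(osc, c(1, 0))
  expect_equal(r$attractor$codes, c(1L, 2L))
  expect_equal(r$attractor$kind, "limit_cycle")
  expect_equal(r$transient, 0L)

  # starting on a fixed point: that fixed point, transient 0
  r <- find_attractor(toggle, c(1, 0))
  expect_equal(r$attractor$codes, 1L)
  expect_equal(r$transient, 0L)
})

test_that("canonical rotation is idempotent and phase-independent", {
  A <- rbind(c(-1L, 1L), c(1L, -1L))
  from_phase1 <- find_attractor(A, c(1, 0))$attractor
  from_phase2 <- find_attractor(A, c(0, 1))$attractor
  expect_identical(from_phase1$codes, from_phase2$codes)
  expect_equal(from_phase1$codes[1], min(from_phase1$codes))
  # longer cycles from random networks canonicalize identically from any phase
  set.seed(91)
  for (k in 1:30) {
    B <- random_tbn(5, 0.5)
    r <- find_attractor(B, decode_state(sample(0:31, 1), 5))
    if (r$attractor$length > 1) {
      phases <- lapply(r$attractor$codes, function(cd)
        find_attractor(B, decode_state(cd, 5))$attractor$codes)
      for (p in phases) expect_identical(p, r$attractor$codes)
    }
  }
})

test_that("exhaustive enumeration matches spec'd small cases and covers the state space", {
  toggle <- rbind(c(0L, -1L), c(-1L, 0L))
  keys <- vapply(enumerate_attractors(toggle), `[[`, character(1), "key")
  expect_setequal(keys, c("0", "1", "2"))

  expect_length(enumerate_attractors(matrix(0L, 2, 2)), 4)

  osc <- rbind(c(-1L, 1L), c(1L, -1L))
  keys <- vapply(enumerate_attractors(osc), `[[`, character(1), "key")
  expect_setequal(keys, c("0", "1-2", "3"))

  # completeness: every trajectory lands on an enumerated attractor
  set.seed(14)
  for (k in 1:20) {
    n <- sample(3:6, 1)
    A <- random_tbn(n, 0.5)
    enum_keys <- vapply(enumerate_attractors(A), `[[`, character(1), "key")
    for (s in 0:(2^n - 1)) {
      r <- find_attractor(A, decode_state(s, n))
      expect_true(r$attractor$key %in% enum_keys)
      expect_lte(r$transient, 2^n)
    }
  }
})

test_that("enumeration agrees with the brute-force oracle on seeded 5-node networks", {
  for (s in 1:400) {
    A <- random_tbn(5, 0.5, seed = 100000 + s)
    pkg_keys <- vapply(enumerate_attractors(A), `[[`, character(1), "key")
    expect_identical(pkg_keys, oracle_attractors(A)$keys)
  }
})

test_that("edge balance counts positive and negative interactions", {
  expect_equal(edge_balance(rbind(c(0L, -1L), c(-1L, 0L))),
               list(n_pos = 0L, n_neg = 2L, balance = -2L))
  expect_equal(edge_balance(matrix(0L, 3, 3))$balance, 0L)
  expect_equal(edge_balance(rbind(c(-1L, 1L), c(1L, -1L))),
               list(n_pos = 2L, n_neg = 2L, balance = 0L))
})

test_that("random networks are seed-reproducible with the requested density", {
  expect_identical(random_tbn(6, 0.4, seed = 3), random_tbn(6, 0.4, seed = 3))
  expect_true(all(random_tbn(4, 0, seed = 1) == 0L))
  expect_equal(sum(random_tbn(5, 1, seed = 2) != 0L), 25)
  expect_error(random_tbn(4, 1.5), class = "tbn_invalid_input")
  # density is a per-entry probability; check the realized rate at n large
  A <- random_tbn(24, 0.5, seed = 9)
  expect_gt(mean(A != 0L), 0.4)
  expect_lt(mean(A != 0L), 0.6)
})

test_that("edge deletion changes exactly one entry and validates its target", {
  toggle <- rbind(c(0L, -1L), c(-1L, 0L))
  expect_equal(delete_edge(toggle, 1, 2), rbind(c(0L, 0L), c(-1L, 0L)))
  B <- delete_edge(toggle, 2, 1)
  expect_equal(sum(B != toggle), 1)
  expect_error(delete_edge(toggle, 1, 1), class = "tbn_invalid_input")

  muts <- deletion_mutants(toggle)
  expect_length(muts, 2)
  # row-major ordering of positions
  expect_equal(vapply(muts, function(m) c(m$i, m$j), integer(2)),
               rbind(c(1L, 2L), c(2L, 1L)))
  expect_length(deletion_mutants(random_tbn(5, 1, seed = 4)), 25)
  expect_error(deletion_mutants(matrix(0L, 3, 3)),
               class = "tbn_degenerate_input")
})

test_that("edge mutation reassigns one uniformly chosen entry to a uniformly chosen other value", {
  set.seed(8)
  A <- random_tbn(4, 0.5)
  for (k in 1:50) {
    mv <- mutate_edge(A)
    expect_equal(sum(mv$matrix != A), 1)
    expect_equal(mv$matrix[mv$i, mv$j], mv$to)
    expect_true(mv$to %in% setdiff(c(-1L, 0L, 1L), A[mv$i, mv$j]))
  }
  # on a 1x1 zero matrix the outcome is -1 or +1 with probability 1/2 each
  set.seed(77)
  draws <- replicate(10000, mutate_edge(matrix(0L, 1, 1))$to)
  n_pos <- sum(draws == 1L)
  ci <- qbinom(c(0.0005, 0.9995), 10000, 0.5)
  expect_gte(n_pos, ci[1])
  expect_lte(n_pos, ci[2])
  # seeded reproducibility
  set.seed(5); a <- mutate_edge(A)
  set.seed(5); b <- mutate_edge(A)
  expect_identical(a, b)
})

test_that("state encoding puts gene 1 in the least significant bit", {
  expect_equal(encode_state(c(1, 0, 1)), 5)
  expect_equal(decode_state(5, 3), c(1L, 0L, 1L))
  for (s in 0:15) expect_equal(encode_state(decode_state(s, 4)), s)
})
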