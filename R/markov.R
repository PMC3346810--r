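#' Markov transition matrix of an Ergodic Set
#'
#' The flip process on an ES is a Markov chain whose states are the member
#' attractors. From an attractor with `L` states there are `L * n` possible
#' single-gene flips; time is assumed to be spent uniformly across the
#' states of a limit cycle, so without the penalty the transition
#' probability to attractor `b` is simply `count(a -> b) / (L * n)` — the
#' flip counts normalized by both the transition multiplicity and the
#' length of the originating cycle.
#'
#' With `use_penalty = TRUE`, flips that oppose active regulation (turning a
#' gene on while its field is negative, or off while positive) receive
#' weight `lambda` instead of 1 before the per-attractor normalization,
#' giving the penalized chain whose stationary vector down-weights
#' biologically unlikely transitions. `lambda = 1` reproduces the plain
#' chain exactly.
#'
#' @param es a `tbn_es` (or a bare list with `attractor_indices`).
#' @param graph the `tbn_graph` the ES was extracted from.
#' @param lambda penalty weight in `(0, 1]`.
#' @param use_penalty logical.
#' @return a row-stochastic matrix over the ES members, rows and columns
#'   named by attractor key.
#' @examples
#' A <- rbind(c(0, -1), c(-1, 0))
#' g <- attractor_graph(A)
#' es <- ergodic_sets(g)[[1]]
#' transition_matrix(es, g)
#' @export
transition_matrix <- function(es, graph, lambda = 0.5, use_penalty = TRUE) {
  check_lambda(lambda)
  idx <- es$attractor_indices
  tr <- graph$transitions
  outside <- tr$from %in% idx & !(tr$to %in% idx)
  if (any(outside))
    stop_invalid("the given attractor set is not terminal in the graph")
  keys <- vapply(graph$attractors[idx], `[[`, character(1), "key")
  P <- matrix(0, length(idx), length(idx), dimnames = list(keys, keys))
  for (r in seq_along(idx)) {
    rows <- tr[tr$from == idx[r], ]
    w <- ifelse(use_penalty & rows$penalized, lambda, 1)
    for (k in seq_len(nrow(rows))) {
      cc <- match(rows$to[k], idx)
      P[r, cc] <- P[r, cc] + w[k]
    }
    P[r, ] <- P[r, ] / sum(w)
  }
  P
}

#' Stationary distribution of a finite Markov chain
#'
#' Solves the balance equations `pi P = pi`, `sum(pi) = 1` by a direct
#' linear solve on the transposed system with the normalization constraint
#' replacing one redundant equation. A direct solve (rather than power
#' iteration) is used because the flip chain of an ES can be periodic; the
#' stationary vector of an irreducible finite chain always exists even when
#' the limit distribution does not.
#'
#' @param P a row-stochastic matrix, irreducible (guaranteed when it comes
#'   from an Ergodic Set).
#' @return a probability vector named like `P`'s rows, satisfying
#'   `pi P = pi` to machine precision.
#' @export
stationary_distribution <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop_invalid("P must be a square matrix")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop_invalid("P must be row-stochastic")
  m <- nrow(P)
  if (m == 1) {
    pi <- 1
  } else {
    M <- t(P) - diag(m)
    M[m, ] <- 1
    b <- c(rep(0, m - 1), 1)
    pi <- tryCatch(solve(M, b), error = function(e)
      stop(errorCondition(
        paste0("stationary solve failed (chain may be reducible): ",
               conditionMessage(e)),
        class = "tbn_numerical_error")))
  }
  if (any(pi < -1e-10))
    stop(errorCondition("stationary solve produced negative probabilities",
                        class = "tbn_numerical_error"))
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  names(pi) <- rownames(P)
  pi
}

#' Mean attractor length of an Ergodic Set
#'
#' The length of an attractor is the number of states in it; this is the
#' unweighted arithmetic mean over the ES members. Its inverse is the
#' discount factor `D` used to penalize sensitivity achieved solely through
#' long limit cycles (see [discounted_fitness()]).
#'
#' @param es a `tbn_es`.
#' @return mean length, at least 1.
#' @export
mean_attractor_length <- function(es) {
  mean(vapply(es$attractors, `[[`, integer(1), "length"))
}
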