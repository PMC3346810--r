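#' Distance between two Ergodic Sets
#'
#' Total-variation distance between the stationary occupancies of two ESs,
#' `d = 1/2 * sum over attractors |pi_A(c) - pi_B(c)|`, taken over the union
#' of member attractors with probability 0 for non-members. Attractors are
#' matched by canonical identity (their exact state sequence): two cycles
#' sharing some states but not identical are distinct. `d` ranges from 0
#' (identical long-term dynamics) to 1 (disjoint attractor support) and
#' measures how differently the two networks distribute their long-run time
#' across attractors.
#'
#' @param es_a,es_b `tbn_es` objects carrying stationary distributions.
#' @return a number in `[0, 1]`.
#' @export
es_distance <- function(es_a, es_b) {
  keys <- union(es_a$keys, es_b$keys)
  pa <- ifelse(keys %in% es_a$keys, es_a$stationary[keys], 0)
  pb <- ifelse(keys %in% es_b$keys, es_b$stationary[keys], 0)
  pa[is.na(pa)] <- 0
  pb[is.na(pb)] <- 0
  sum(abs(pa - pb)) / 2
}

#' Four-way decomposition of displaced probability mass
#'
#' A deletion mutant `B` displaces the wild type's stationary mass in four
#' ways:
#' 1. a wild-type ES attractor is destabilized — no longer an attractor of
#'    `B` at all (its mass `pi_A` is lost);
#' 2. mass appears on an attractor of `B`'s ES that was not in the
#'    wild-type ES;
#' 3. a wild-type ES attractor is retained as an attractor of `B` but
#'    excluded from `B`'s ES;
#' 4. mass is redistributed across attractors present in both ESs.
#'
#' The four contributions sum to `2 d`, twice the total-variation distance,
#' since each unit of moved mass is counted once where it left and once
#' where it landed.
#'
#' @param es_a wild-type ES with stationary distribution.
#' @param es_b mutant ES with stationary distribution.
#' @param attractors_b the full attractor set of the mutant network: a list
#'   of attractor objects or a character vector of keys.
#' @return named numeric vector `c(m1, m2, m3, m4)`.
#' @export
displacement_decomposition <- function(es_a, es_b, attractors_b) {
  keys_b <- if (is.character(attractors_b)) attractors_b
            else vapply(attractors_b, `[[`, character(1), "key")
  m1 <- m3 <- m4 <- 0
  for (k in seq_along(es_a$keys)) {
    key <- es_a$keys[k]
    p <- es_a$stationary[[k]]
    if (!(key %in% keys_b)) m1 <- m1 + p
    else if (!(key %in% es_b$keys)) m3 <- m3 + p
    else m4 <- m4 + abs(p - es_b$stationary[[match(key, es_b$keys)]])
  }
  m2 <- sum(es_b$stationary[!(es_b$keys %in% es_a$keys)])
  c(m1 = m1, m2 = m2, m3 = m3, m4 = m4)
}

#' Edge-deletion sensitivity of a network
#'
#' For every single-edge deletion mutant of `A`, the distance `d` between
#' the wild-type Ergodic Set occupancy and the mutant's is computed; the
#' sensitivity `S` is the mean of `d` over all evaluated mutants. `S = 0`
#' means maximally robust (no deletion changes the long-term dynamics),
#' `S = 1` maximally sensitive. The report also carries the four-way
#' displacement decomposition per mutant (see
#' [displacement_decomposition()]).
#'
#' Sensitivity is only defined for networks with exactly one ES; a
#' multi-ES wild type raises an error. Mutants with multiple ESs are rare;
#' by default (`multi_es_policy = "skip_mutant"`) they are excluded from
#' the mean and listed in `skipped`.
#'
#' @param A interaction matrix with at least one edge and a single ES.
#' @param lambda penalty weight in `(0, 1]` for flips opposing active
#'   regulation.
#' @param use_penalty logical; `TRUE` (default) scores distances on the
#'   penalized stationary distribution.
#' @param multi_es_policy `"skip_mutant"` or `"error"`.
#' @return a `tbn_sensitivity` object: list with `S`, `discounted_fitness`
#'   (`S` times the inverse mean wild-type ES attractor length),
#'   `wt_es_size`, `wt_mean_length`, a `per_mutant` data frame
#'   (`i`, `j`, `d`, `m1`..`m4`, `mutant_es_size`, `mutant_mean_length`),
#'   a `skipped` data frame, `lambda` and `use_penalty`.
#' @examples
#' rep <- deletion_sensitivity(rbind(c(0, -1), c(-1, 0)), lambda = 1)
#' rep$S # 0.25
#' @export
deletion_sensitivity <- function(A, lambda = 0.5, use_penalty = TRUE,
                                 multi_es_policy = c("skip_mutant", "error")) {
  A <- check_tbn(A)
  check_capacity(nrow(A))
  check_lambda(lambda)
  multi_es_policy <- match.arg(multi_es_policy)
  if (all(A == 0L))
    stop_degenerate("sensitivity is undefined for a network with no edges")
  res <- cpp_sensitivity(A, lambda, use_penalty, TRUE)
  if (res$n_es != 1L)
    stop_multi_es(sprintf(
      "sensitivity is not well defined: the network has %d Ergodic Sets",
      res$n_es))
  if (multi_es_policy == "error" && length(res$skipped_i) > 0)
    stop_multi_es(sprintf("%d deletion mutant(s) have multiple Ergodic Sets",
                          length(res$skipped_i)))
  per_mutant <- data.frame(
    i = as.integer(res$mutant_i), j = as.integer(res$mutant_j),
    d = as.numeric(res$d),
    m1 = as.numeric(res$m1), m2 = as.numeric(res$m2),
    m3 = as.numeric(res$m3), m4 = as.numeric(res$m4),
    mutant_es_size = as.integer(res$mutant_es_size),
    mutant_mean_length = as.numeric(res$mutant_mean_length))
  skipped <- data.frame(i = as.integer(res$skipped_i),
                        j = as.integer(res$skipped_j),
                        reason = rep("multi_es", length(res$skipped_i)))
  structure(
    list(S = res$S,
         discounted_fitness = res$S / res$wt_mean_length,
         wt_es_size = res$wt_es_size,
         wt_mean_length = res$wt_mean_length,
         n_edges = res$n_edges,
         n_evaluated = res$n_evaluated,
         per_mutant = per_mutant,
         skipped = skipped,
         lambda = lambda,
         use_penalty = use_penalty),
    class = "tbn_sensitivity")
}

#' @export
print.tbn_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<deletion sensitivity: S = %.4f over %d/%d mutants (lambda = %g%s)>\n",
    x$S, x$n_evaluated, x$n_edges, x$lambda,
    if (x$use_penalty) ", penalized" else ""))
  cat(sprintf("  wild-type ES: %d attractor(s), mean length %.3g; S x D = %.4f\n",
              x$wt_es_size, x$wt_mean_length, x$discounted_fitness))
  if (nrow(x$skipped) > 0)
    cat(sprintf("  %d mutant(s) skipped (multiple Ergodic Sets)\n",
                nrow(x$skipped)))
  invisible(x)
}

#' Limit-cycle-discounted sensitivity
#'
#' `S(A) * D` where `D = 1 / mean_attractor_length(ES)` of the wild type.
#' `D` weighs down the score of networks whose ES is dominated by long
#' limit cycles, which are trivially easy to destabilize; it equals 1 (no
#' discount) exactly when the ES holds only fixed points.
#'
#' @inheritParams deletion_sensitivity
#' @return the discounted score, in `[0, 1]`.
#' @export
discounted_fitness <- function(A, lambda = 0.5, use_penalty = TRUE,
                               multi_es_policy = c("skip_mutant", "error")) {
  deletion_sensitivity(A, lambda, use_penalty,
                       multi_es_policy)$discounted_fitness
}
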