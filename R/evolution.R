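#' Adaptive-walk evolution of sensitivity or robustness
#'
#' A simple hill climb over single-edge changes. At each step one entry of
#' the current matrix is selected uniformly and reassigned to one of the
#' two other ternary values with equal probability. The proposal's fitness
#' (the sensitivity `S`, or `S * D` with the limit-cycle discount) is
#' computed and the proposal accepted only if it strictly improves the
#' objective; otherwise the current matrix is retained. Proposals whose
#' network has more than one Ergodic Set — for which sensitivity is not
#' well defined — are rejected outright but still consume a move from the
#' budget. Up to `max_steps` moves are attempted; walks typically reach a
#' local fitness peak well before that.
#'
#' @param A0 starting interaction matrix; must have exactly one ES.
#' @param objective `"maximize"` (sensitivity) or `"minimize"` (robustness).
#' @param use_discount logical; optimize `S * D` instead of `S`, where `D`
#'   is the inverse mean attractor length of the wild-type ES.
#' @param max_steps mutational move budget (default 1000).
#' @param lambda,use_penalty Markov chain settings passed to the
#'   sensitivity evaluation.
#' @param stop_at_optimum stop early once fitness reaches 1 (maximize) or 0
#'   (minimize) within 1e-12.
#' @param seed optional integer seed; when given, the walk is reproducible
#'   and the global RNG state is restored afterwards.
#' @param record_steps keep the per-step proposal log (set `FALSE` to save
#'   memory in large ensembles).
#' @return a `tbn_walk`: list with `initial`, `final` matrices, `fitness`
#'   (final), `initial_fitness`, `fitness_history` (accepted values,
#'   starting with the initial fitness), `n_accepted`, `n_proposed`,
#'   `final_S`, `final_es_size`, `final_mean_length`, and (if recorded)
#'   `steps`, a data frame logging every proposal.
#' @examples
#' \donttest{
#' w <- adaptive_walk(random_tbn(5, seed = 7), "minimize", seed = 7,
#'                    max_steps = 200)
#' w$fitness <= w$initial_fitness
#' }
#' @export
adaptive_walk <- function(A0, objective = c("maximize", "minimize"),
                          use_discount = FALSE, max_steps = 1000,
                          lambda = 0.5, use_penalty = TRUE,
                          stop_at_optimum = TRUE, seed = NULL,
                          record_steps = TRUE) {
  A0 <- check_tbn(A0)
  check_capacity(nrow(A0))
  check_lambda(lambda)
  objective <- match.arg(objective)
  if (max_steps < 1) stop_invalid("max_steps must be at least 1")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }

  eval_fitness <- function(M) {
    res <- cpp_sensitivity(M, lambda, use_penalty, FALSE)
    if (res$n_es != 1L)
      return(list(ok = FALSE, reason = "multi_es", n_es = res$n_es))
    if (is.na(res$S))
      return(list(ok = FALSE, reason = "undefined_S", n_es = 1L))
    f <- if (use_discount) res$S / res$wt_mean_length else res$S
    list(ok = TRUE, fitness = f, S = res$S, es_size = res$wt_es_size,
         mean_length = res$wt_mean_length, n_es = 1L)
  }
  better <- if (objective == "maximize") {
    function(f, cur) f > cur
  } else {
    function(f, cur) f < cur
  }
  at_optimum <- function(f) {
    if (objective == "maximize") f >= 1 - 1e-12 else f <= 1e-12
  }

  cur <- eval_fitness(A0)
  if (!cur$ok) {
    if (cur$reason == "multi_es")
      stop_multi_es("the starting network has multiple Ergodic Sets")
    stop_degenerate("the starting network has an undefined sensitivity")
  }
  A <- A0
  init <- cur
  history <- cur$fitness
  steps <- if (record_steps) vector("list", max_steps) else NULL
  n_acc <- 0L
  n_prop <- 0L

  if (!(stop_at_optimum && at_optimum(cur$fitness))) {
    for (step in seq_len(max_steps)) {
      mv <- mutate_edge(A)
      n_prop <- n_prop + 1L
      ev <- eval_fitness(mv$matrix)
      accepted <- ev$ok && better(ev$fitness, cur$fitness)
      reason <- if (!ev$ok) ev$reason
                else if (!accepted) "no_improvement" else ""
      if (record_steps)
        steps[[step]] <- data.frame(
          step = step, i = mv$i, j = mv$j, from = mv$from, to = mv$to,
          n_es = ev$n_es,
          fitness = if (ev$ok) ev$fitness else NA_real_,
          accepted = accepted,
          reason = reason)
      if (accepted) {
        A <- mv$matrix
        cur <- ev
        history <- c(history, ev$fitness)
        n_acc <- n_acc + 1L
        if (stop_at_optimum && at_optimum(cur$fitness)) break
      }
    }
  }

  structure(
    list(initial = A0, final = A,
         objective = objective, use_discount = use_discount,
         lambda = lambda, use_penalty = use_penalty,
         max_steps = max_steps, seed = seed,
         initial_fitness = history[1], fitness = cur$fitness,
         fitness_history = history,
         initial_S = init$S, initial_es_size = init$es_size,
         initial_mean_length = init$mean_length,
         final_S = cur$S, final_es_size = cur$es_size,
         final_mean_length = cur$mean_length,
         n_accepted = n_acc, n_proposed = n_prop,
         steps = if (record_steps)
           do.call(rbind, steps[!vapply(steps, is.null, logical(1))])
         else NULL),
    class = "tbn_walk")
}

#' @export
print.tbn_walk <- function(x, ...) {
  cat(sprintf(
    "<adaptive walk (%s%s): fitness %.4f -> %.4f in %d accepted / %d proposed moves>\n",
    x$objective, if (x$use_discount) ", discounted" else "",
    x$initial_fitness, x$fitness, x$n_accepted, x$n_proposed))
  invisible(x)
}

#' Single-edge changes that switch the Ergodic Set count
#'
#' Scans all `2 n^2` single-entry reassignments of `A` and returns those
#' whose network has a different number of Ergodic Sets than `A`. Such
#' edits switch a network between a single ES and multiple ESs — the kind
#' of one-mutation change proposed to underlie stochastic differentiation.
#'
#' @param A interaction matrix.
#' @return a data frame with `i`, `j`, `from`, `to`, `es_before`,
#'   `es_after`; zero rows when no edit switches the count.
#' @export
es_switch_scan <- function(A) {
  A <- check_tbn(A)
  check_capacity(nrow(A))
  n <- nrow(A)
  base <- cpp_count_es(A)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (v in setdiff(c(-1L, 0L, 1L), A[i, j])) {
        B <- A
        B[i, j] <- v
        cnt <- cpp_count_es(B)
        if (cnt != base)
          rows[[length(rows) + 1L]] <- data.frame(
            i = i, j = j, from = A[i, j], to = v,
            es_before = base, es_after = cnt)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(0), j = integer(0), from = integer(0),
                      to = integer(0), es_before = integer(0),
                      es_after = integer(0)))
  do.call(rbind, rows)
}
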