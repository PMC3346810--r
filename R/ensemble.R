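#' Run an ensemble of adaptive-walk evolutions
#'
#' Draws `n_networks` random starting networks (redrawing, with a logged
#' count, any whose Ergodic Set count is not 1), evolves each with
#' [adaptive_walk()], and aggregates initial and evolved statistics:
#' sensitivity, edge balance, ES size and mean attractor length, and —
#' when `detail = TRUE` — the per-network four-way displacement shares of
#' the evolved sensitivity.
#'
#' Reproducibility: per-run seeds are drawn once from the master `seed` and
#' recorded in the output, so any single run can be re-executed in
#' isolation with `adaptive_walk(seed = runs$seed[k], ...)` after redrawing
#' its starting network the same way.
#'
#' @param n_networks number of independent runs.
#' @param n_genes network size.
#' @param density edge density of the starting networks.
#' @param objective,use_discount,max_steps,lambda,use_penalty passed to
#'   [adaptive_walk()].
#' @param seed master seed (required for a reproducible ensemble).
#' @param detail compute the displacement decomposition of every evolved
#'   network (needed for [decomposition_summary()]).
#' @return a `tbn_ensemble`: list with `config`, `runs` (one-row-per-run
#'   data frame) and `n_redrawn`, the count of multi-ES starting networks
#'   that were discarded and redrawn.
#' @export
run_ensemble <- function(n_networks, n_genes = 5, density = 0.5,
                         objective = c("maximize", "minimize"),
                         use_discount = FALSE, max_steps = 1000,
                         lambda = 0.5, use_penalty = TRUE,
                         seed = NULL, detail = FALSE) {
  objective <- match.arg(objective)
  if (n_networks < 1) stop_invalid("n_networks must be at least 1")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  run_seeds <- sample.int(.Machine$integer.max, n_networks)
  rows <- vector("list", n_networks)
  n_redrawn <- 0L
  for (k in seq_len(n_networks)) {
    set.seed(run_seeds[k])
    repeat {
      A0 <- random_tbn(n_genes, density)
      if (any(A0 != 0L) && cpp_count_es(A0) == 1L) break
      n_redrawn <- n_redrawn + 1L
    }
    w <- adaptive_walk(A0, objective, use_discount = use_discount,
                       max_steps = max_steps, lambda = lambda,
                       use_penalty = use_penalty, record_steps = FALSE)
    bal0 <- edge_balance(A0)
    bal1 <- edge_balance(w$final)
    row <- data.frame(
      run = k, seed = run_seeds[k],
      initial_S = w$initial_S, final_S = w$final_S,
      initial_fitness = w$initial_fitness, final_fitness = w$fitness,
      initial_balance = bal0$balance, final_balance = bal1$balance,
      initial_edges = bal0$n_pos + bal0$n_neg,
      final_edges = bal1$n_pos + bal1$n_neg,
      initial_es_size = w$initial_es_size, final_es_size = w$final_es_size,
      initial_mean_length = w$initial_mean_length,
      final_mean_length = w$final_mean_length,
      n_accepted = w$n_accepted, n_proposed = w$n_proposed,
      at_optimum = if (objective == "maximize") w$fitness >= 1 - 1e-12
                   else w$fitness <= 1e-12)
    if (detail) {
      rep <- deletion_sensitivity(w$final, lambda = lambda,
                                  use_penalty = use_penalty)
      pm <- rep$per_mutant
      # absolute contribution of each displacement method to this network's
      # S: a mutant contributes m_k / 2 to its distance d, S is the mean d,
      # so the four contributions sum to S exactly
      if (nrow(pm) > 0) {
        row$contrib_m12 <- mean((pm$m1 + pm$m2) / 2)
        row$contrib_m3 <- mean(pm$m3 / 2)
        row$contrib_m4 <- mean(pm$m4 / 2)
      } else {
        row$contrib_m12 <- row$contrib_m3 <- row$contrib_m4 <- NA_real_
      }
      row$n_skipped_mutants <- nrow(rep$skipped)
    }
    rows[[k]] <- row
  }
  structure(
    list(config = list(n_networks = n_networks, n_genes = n_genes,
                       density = density, objective = objective,
                       use_discount = use_discount, max_steps = max_steps,
                       lambda = lambda, use_penalty = use_penalty,
                       seed = seed, detail = detail),
         runs = do.call(rbind, rows),
         n_redrawn = n_redrawn),
    class = "tbn_ensemble")
}

#' @export
print.tbn_ensemble <- function(x, ...) {
  r <- x$runs
  cat(sprintf(
    "<ensemble: %d x %d-gene networks, %s%s>\n",
    x$config$n_networks, x$config$n_genes, x$config$objective,
    if (x$config$use_discount) " (discounted)" else ""))
  cat(sprintf("  S: initial mean %.4f -> evolved mean %.4f; %d at optimum\n",
              mean(r$initial_S), mean(r$final_S), sum(r$at_optimum)))
  invisible(x)
}

#' Displacement-mass summary over an evolved ensemble
#'
#' Restricts a `detail = TRUE` ensemble to evolved networks whose
#' sensitivity meets `min_S` and averages each network's contribution to
#' `S` from displacement methods 1&2 (attractor destabilized / new
#' attractor in the mutant ES), 3 (retained but excluded from the mutant
#' ES) and 4 (redistribution over shared attractors). Contributions are in
#' units of `S` — for each network the four sum to its `S` exactly, so the
#' reported means sum to the subset's mean sensitivity — which is how the
#' displaced-mass breakdown of evolved ensembles is conventionally quoted.
#'
#' @param ensemble a `tbn_ensemble` run with `detail = TRUE`.
#' @param min_S minimum evolved sensitivity for the subset (default 0.5).
#' @return a list with `n` (subset size), `min_S`, `mean_S`, and mean
#'   contributions `methods_12`, `method_3`, `method_4`; `n = 0` flags an
#'   empty subset (all statistics `NA`, no division attempted).
#' @export
decomposition_summary <- function(ensemble, min_S = 0.5) {
  r <- ensemble$runs
  if (is.null(r$contrib_m12))
    stop_invalid("ensemble was not run with detail = TRUE")
  sub <- r[!is.na(r$contrib_m12) & r$final_S >= min_S, ]
  if (nrow(sub) == 0)
    return(list(n = 0L, min_S = min_S, mean_S = NA_real_,
                methods_12 = NA_real_, method_3 = NA_real_,
                method_4 = NA_real_))
  list(n = nrow(sub), min_S = min_S, mean_S = mean(sub$final_S),
       methods_12 = mean(sub$contrib_m12),
       method_3 = mean(sub$contrib_m3),
       method_4 = mean(sub$contrib_m4))
}

#' Built-in example networks
#'
#' Small hand-analysed networks used throughout the documentation and
#' tests: the mutual-repression toggle switch, the cross-coupled
#' oscillator, the all-zero two-gene network, and a seeded set of random
#' five-gene networks. For the first three, the attractor state codes, ES
#' size and stationary distribution (penalty-independent in these cases)
#' are included as independently hand-derived expectations.
#'
#' @return a named list of fixtures; each has `matrix` and, where
#'   hand-derived, `expected` (list with `attractor_keys`, `n_es`,
#'   `es_size`, `pi`).
#' @export
tbn_fixtures <- function() {
  list(
    toggle = list(
      matrix = rbind(c(0L, -1L), c(-1L, 0L)),
      expected = list(
        attractor_keys = c("0", "1", "2"), n_es = 1L, es_size = 3L,
        pi = c("0" = 0.5, "1" = 0.25, "2" = 0.25))),
    oscillator = list(
      matrix = rbind(c(-1L, 1L), c(1L, -1L)),
      expected = list(
        attractor_keys = c("0", "1-2", "3"), n_es = 1L, es_size = 3L,
        pi = c("0" = 0.25, "1-2" = 0.5, "3" = 0.25))),
    zero2 = list(
      matrix = matrix(0L, 2, 2),
      expected = list(
        attractor_keys = c("0", "1", "2", "3"), n_es = 1L, es_size = 4L,
        pi = c("0" = 0.25, "1" = 0.25, "2" = 0.25, "3" = 0.25))),
    random5 = list(
      matrices = lapply(1:20, function(s) random_tbn(5, 0.5, seed = 1000 + s)))
  )
}
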