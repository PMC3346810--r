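#' Flip-transition graph among attractors
#'
#' From every state of every attractor, each of the `n` single-gene flips
#' is applied and the deterministic dynamics followed to whichever attractor
#' is reached (possibly the same one). The resulting directed multigraph over
#' attractors captures how weak expression noise moves the system between
#' its long-term behaviours. Self-transitions are recorded.
#'
#' Each transition carries a `penalized` flag: flipping a gene on while its
#' regulatory field is negative (other genes actively repress it), or off
#' while the field is positive, is biologically unlikely; the flag is
#' evaluated at the pre-flip state and later down-weights such transitions
#' in the Markov chain (see [transition_matrix()]). The flag never removes a
#' transition, so the graph topology is penalty-free.
#'
#' @param A interaction matrix.
#' @return a `tbn_graph`: list with `n`, `matrix`, `attractors` (list of
#'   [tbn_attractor][find_attractor] objects) and `transitions`, a data
#'   frame with one row per (attractor state, flipped gene) pair holding
#'   `from`, `to` (attractor indices), `state` (source state code), `gene`
#'   and `penalized`.
#' @examples
#' g <- attractor_graph(rbind(c(0, -1), c(-1, 0)))
#' nrow(g$transitions) # 3 fixed points x 2 genes = 6 flips
#' @export
attractor_graph <- function(A) {
  A <- check_tbn(A)
  n <- nrow(A)
  check_capacity(n)
  res <- cpp_analyze(A, 1.0, FALSE)
  attractors <- lapply(res$attractors, new_attractor, n = n)
  attr_of <- res$attr_of_state  # indexed by state code + 1

  from <- to <- state <- gene <- integer(0)
  pen <- logical(0)
  for (a in seq_along(attractors)) {
    for (s in attractors[[a]]$codes) {
      bits <- decode_state(s, n)
      h <- as.vector(A %*% bits)
      for (g in seq_len(n)) {
        flipped <- bitwXor(s, bitwShiftL(1L, g - 1L))
        flip_on <- bits[g] == 0L
        from <- c(from, a)
        to <- c(to, attr_of[flipped + 1L])
        state <- c(state, s)
        gene <- c(gene, g)
        pen <- c(pen, (flip_on && h[g] < 0) || (!flip_on && h[g] > 0))
      }
    }
  }
  structure(
    list(n = n, matrix = A, attractors = attractors,
         transitions = data.frame(from = from, to = to, state = state,
                                  gene = gene, penalized = pen)),
    class = "tbn_graph")
}

#' @export
print.tbn_graph <- function(x, ...) {
  cat(sprintf("<flip-transition graph: %d genes, %d attractors, %d flips>\n",
              x$n, length(x$attractors), nrow(x$transitions)))
  invisible(x)
}

new_ergodic_set <- function(graph, indices, lambda = 0.5, use_penalty = TRUE) {
  members <- graph$attractors[indices]
  es <- structure(
    list(attractor_indices = indices, attractors = members,
         size = length(indices),
         keys = vapply(members, `[[`, character(1), "key"),
         stationary = NULL, lambda = lambda, use_penalty = use_penalty),
    class = "tbn_es")
  P <- transition_matrix(es, graph, lambda = lambda, use_penalty = use_penalty)
  pi <- stationary_distribution(P)
  names(pi) <- es$keys
  es$stationary <- pi
  es
}

#' Ergodic Sets of a network
#'
#' An Ergodic Set (ES) is a strongly connected subset of attractors with no
#' flip transition leaving it: once weak expression noise brings the system
#' into an ES it never leaves, so the ESs describe the network's entire
#' long-term behaviour. They are the terminal strongly connected components
#' of the flip-transition graph; at least one always exists, and more than
#' one is rare for random networks.
#'
#' Each returned ES carries the stationary distribution of its flip-induced
#' Markov chain (see [transition_matrix()] for the chain construction and
#' the role of `lambda`).
#'
#' @param x an interaction matrix or a `tbn_graph` from [attractor_graph()].
#' @param lambda penalty weight in `(0, 1]` for flips opposing active
#'   regulation; `1` disables the penalty's effect.
#' @param use_penalty logical; `FALSE` gives the plain stationary
#'   distribution.
#' @return a list of `tbn_es` objects ordered by the smallest canonical
#'   state code of their members. Each has the member `attractors`, their
#'   `keys`, and the `stationary` probability vector (named by key).
#' @examples
#' ess <- ergodic_sets(rbind(c(0, -1), c(-1, 0)))
#' ess[[1]]$stationary # (1/2, 1/4, 1/4)
#' @export
ergodic_sets <- function(x, lambda = 0.5, use_penalty = TRUE) {
  graph <- if (inherits(x, "tbn_graph")) x else attractor_graph(x)
  check_lambda(lambda)
  tr <- graph$transitions
  nA <- length(graph$attractors)
  # strongly connected components of the attractor digraph
  edges <- unique(tr[, c("from", "to")])
  ig <- igraph::graph_from_data_frame(
    edges, directed = TRUE, vertices = data.frame(name = seq_len(nA)))
  comp <- igraph::components(ig, mode = "strong")$membership
  comp <- comp[as.character(seq_len(nA))]
  # terminal components: no edge leaves them
  leaving <- unique(comp[edges$from[comp[edges$from] != comp[edges$to]]])
  terminal <- setdiff(unique(comp), leaving)
  sets <- lapply(terminal, function(cc) sort(which(comp == cc)))
  sets <- sets[order(vapply(sets, function(s)
    graph$attractors[[s[1]]]$codes[1], numeric(1)))]
  lapply(sets, new_ergodic_set, graph = graph, lambda = lambda,
         use_penalty = use_penalty)
}

#' @export
print.tbn_es <- function(x, ...) {
  cat(sprintf("<Ergodic Set: %d attractor(s), mean length %.3g>\n",
              x$size, mean_attractor_length(x)))
  for (k in seq_len(x$size))
    cat(sprintf("  pi = %.4f  ", x$stationary[k]), format(x$attractors[[k]]$key),
        "\n")
  invisible(x)
}

#' Number of Ergodic Sets
#'
#' Fast count of the terminal strongly connected components of the
#' flip-transition graph. Networks with more than one ES have an undefined
#' sensitivity score and are excluded from evolutionary experiments.
#'
#' @param A interaction matrix.
#' @return integer count, always at least 1.
#' @export
count_ergodic_sets <- function(A) {
  A <- check_tbn(A)
  check_capacity(nrow(A))
  cpp_count_es(A)
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda <= 0 || lambda > 1)
    stop_invalid("lambda must be a single number in (0, 1]")
  invisible(lambda)
}
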