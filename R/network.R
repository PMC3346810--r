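#' Validate a threshold Boolean network interaction matrix
#'
#' An interaction matrix is a square integer matrix with entries in
#' `{-1, 0, +1}`; entry `(i, j)` is the regulatory effect of gene `j` on
#' gene `i` (+1 excitatory, -1 inhibitory, 0 absent). Diagonal entries
#' (self-regulation) are permitted and treated like any other edge.
#'
#' @param entries a square numeric/integer matrix with entries in
#'   `{-1, 0, 1}`.
#' @return the validated matrix, in integer storage mode.
#' @examples
#' toggle <- tbn_network(rbind(c(0, -1), c(-1, 0)))
#' @export
tbn_network <- function(entries) {
  if (!is.matrix(entries)) stop_invalid("`entries` must be a matrix")
  if (nrow(entries) != ncol(entries))
    stop_invalid(sprintf("interaction matrix must be square, got %d x %d",
                         nrow(entries), ncol(entries)))
  if (nrow(entries) < 1) stop_invalid("network must have at least one gene")
  bad <- which(!(entries %in% c(-1, 0, 1)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(entries)) + 1
    j <- ((bad[1] - 1) %/% nrow(entries)) + 1
    stop_invalid(sprintf(
      "entry (%d, %d) is %s; entries must be -1, 0 or 1", i, j,
      format(entries[bad[1]])))
  }
  storage.mode(entries) <- "integer"
  dimnames(entries) <- NULL
  entries
}

check_tbn <- function(A) {
  tbn_network(A)
}

# exhaustive state-space work is bounded to keep memory in check
MAX_GENES <- 24L

check_capacity <- function(n) {
  if (n > MAX_GENES)
    stop_capacity(sprintf(
      "exhaustive state-space analysis is limited to %d genes (got %d)",
      MAX_GENES, n))
  invisible(n)
}

#' Encode and decode gene expression states
#'
#' States are length-`n` binary vectors; the canonical integer code puts
#' gene 1 in the least significant bit, so `c(1, 0)` encodes to 1 and
#' `c(0, 1)` to 2. Codes run from 0 to `2^n - 1`.
#'
#' @param bits binary vector of gene states.
#' @param code integer state code.
#' @param n number of genes.
#' @return `encode_state` returns the integer code; `decode_state` the
#'   binary vector.
#' @examples
#' encode_state(c(1, 0, 1)) # 5
#' decode_state(5, 3)
#' @export
encode_state <- function(bits) {
  if (!all(bits %in% c(0, 1))) stop_invalid("state components must be 0 or 1")
  sum(as.integer(bits) * 2L^(seq_along(bits) - 1L))
}

#' @rdname encode_state
#' @export
decode_state <- function(code, n) {
  as.integer(bitwAnd(bitwShiftR(as.integer(code), 0:(n - 1L)), 1L))
}

#' Synchronous threshold update
#'
#' Computes the successor of state `x`: gene `i` receives the field
#' `h_i = sum_j A[i, j] x_j` and switches on if `h_i > 0`, off if
#' `h_i < 0`, and retains its previous state if `h_i = 0` (a consensus rule
#' under multiple regulatory inputs).
#'
#' @param A interaction matrix.
#' @param x binary state vector of length `nrow(A)`.
#' @return the successor state as a binary vector.
#' @examples
#' tbn_update(rbind(c(0, -1), c(-1, 0)), c(1, 0)) # stays (1, 0)
#' @export
tbn_update <- function(A, x) {
  A <- check_tbn(A)
  if (length(x) != nrow(A))
    stop_invalid(sprintf("state has %d components but the network has %d genes",
                         length(x), nrow(A)))
  if (!all(x %in% c(0, 1))) stop_invalid("state components must be 0 or 1")
  h <- as.vector(A %*% as.integer(x))
  ifelse(h > 0, 1L, ifelse(h < 0, 0L, as.integer(x)))
}

new_attractor <- function(codes, n) {
  codes <- as.integer(codes)
  # canonical rotation: start the cycle at its smallest state code
  k <- which.min(codes)
  if (k > 1) codes <- c(codes[k:length(codes)], codes[seq_len(k - 1)])
  structure(
    list(codes = codes, n = as.integer(n), length = length(codes),
         kind = if (length(codes) == 1) "fixed_point" else "limit_cycle",
         key = paste(codes, collapse = "-")),
    class = "tbn_attractor")
}

#' @export
print.tbn_attractor <- function(x, ...) {
  states <- vapply(x$codes, function(c)
    paste(decode_state(c, x$n), collapse = ""), character(1))
  cat(sprintf("<%s, length %d>: %s\n",
              gsub("_", " ", x$kind), x$length, paste(states, collapse = " -> ")))
  invisible(x)
}

#' Find the attractor reached from a state
#'
#' Iterates the synchronous dynamics from `x0` until a state repeats; the
#' repeated segment is the attractor (fixed point or limit cycle) and the
#' steps taken before entering it are the transient. The dynamics are
#' deterministic on a finite state space, so an attractor is always reached.
#'
#' @param A interaction matrix.
#' @param x0 initial binary state vector.
#' @return a list with `attractor` (a `tbn_attractor`: canonical cycle of
#'   state codes, `length`, `kind`) and `transient`, the number of steps
#'   before the cycle is entered.
#' @examples
#' find_attractor(rbind(c(0, -1), c(-1, 0)), c(1, 1))
#' @export
find_attractor <- function(A, x0) {
  A <- check_tbn(A)
  n <- nrow(A)
  check_capacity(n)
  if (length(x0) != n)
    stop_invalid("initial state length does not match the network size")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- integer(0)
  x <- as.integer(x0)
  code <- encode_state(x)
  repeat {
    key <- as.character(code)
    if (!is.null(seen[[key]])) {
      first <- seen[[key]]
      cycle <- path[first:length(path)]
      return(list(attractor = new_attractor(cycle, n), transient = first - 1L))
    }
    path <- c(path, code)
    seen[[key]] <- length(path)
    x <- tbn_update(A, x)
    code <- encode_state(x)
  }
}

#' Enumerate all attractors of a network
#'
#' Runs the deterministic dynamics from every one of the `2^n` states (with
#' memoization in compiled code) and returns the distinct attractors in
#' canonical form, ordered by their smallest state code. The union of their
#' basins covers the whole state space.
#'
#' @param A interaction matrix with at most 24 genes.
#' @return a list of `tbn_attractor` objects.
#' @examples
#' length(enumerate_attractors(rbind(c(0, -1), c(-1, 0)))) # 3 fixed points
#' @export
enumerate_attractors <- function(A) {
  A <- check_tbn(A)
  check_capacity(nrow(A))
  res <- cpp_analyze(A, 1.0, FALSE)
  lapply(res$attractors, new_attractor, n = nrow(A))
}

#' Count excitatory and inhibitory edges
#'
#' The edge balance `n_pos - n_neg` measures how topologically balanced a
#' network is; evolved sensitive networks tend towards balance near zero.
#'
#' @param A interaction matrix.
#' @return a list with `n_pos`, `n_neg` and `balance = n_pos - n_neg`.
#' @export
edge_balance <- function(A) {
  A <- check_tbn(A)
  n_pos <- sum(A == 1L)
  n_neg <- sum(A == -1L)
  list(n_pos = n_pos, n_neg = n_neg, balance = n_pos - n_neg)
}

#' Draw a random threshold Boolean network
#'
#' Each entry is independently 0 with probability `1 - density` and
#' otherwise +1 or -1 with equal probability. Uses R's RNG; pass `seed` (or
#' call `set.seed()` beforehand) for reproducibility. When `seed` is given
#' the global RNG state is restored on exit.
#'
#' @param n number of genes.
#' @param density probability that an entry is nonzero, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return an `n` by `n` interaction matrix.
#' @examples
#' A <- random_tbn(5, density = 0.5, seed = 1)
#' @export
random_tbn <- function(n, density = 0.5, seed = NULL) {
  if (n < 1) stop_invalid("n must be at least 1")
  if (!is.numeric(density) || length(density) != 1 ||
      is.na(density) || density < 0 || density > 1)
    stop_invalid("density must be a single number in [0, 1]")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  signs <- sample(c(-1L, 1L), n * n, replace = TRUE)
  present <- runif(n * n) < density
  matrix(ifelse(present, signs, 0L), n, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Delete one interaction edge
#'
#' Returns the deletion mutant of `A` with entry `(i, j)` set to zero; all
#' other entries are unchanged. The entry must currently be nonzero.
#'
#' @param A interaction matrix.
#' @param i,j row (target gene) and column (source gene) of the edge.
#' @return the mutant interaction matrix.
#' @export
delete_edge <- function(A, i, j) {
  A <- check_tbn(A)
  if (i < 1 || i > nrow(A) || j < 1 || j > nrow(A))
    stop_invalid("edge position out of range")
  if (A[i, j] == 0L)
    stop_invalid(sprintf("entry (%d, %d) is already zero; not an edge", i, j))
  A[i, j] <- 0L
  A
}

#' All single-edge deletion mutants
#'
#' One mutant per nonzero entry of `A`, in row-major order of positions.
#'
#' @param A interaction matrix with at least one nonzero entry.
#' @return a list of `list(i, j, matrix)` records.
#' @export
deletion_mutants <- function(A) {
  A <- check_tbn(A)
  if (all(A == 0L))
    stop_degenerate("the all-zero network has no edges to delete")
  out <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (A[i, j] != 0L)
        out[[length(out) + 1L]] <- list(i = i, j = j,
                                        matrix = delete_edge(A, i, j))
    }
  }
  out
}

#' Random single-edge mutation
#'
#' Picks a position uniformly over all `n^2` entries and reassigns it to one
#' of the two other ternary values with equal probability, so exactly one
#' entry changes. This is the proposal move of the adaptive walk.
#'
#' @param A interaction matrix.
#' @return a list with the mutated `matrix` and the changed position
#'   (`i`, `j`, `from`, `to`).
#' @export
mutate_edge <- function(A) {
  A <- check_tbn(A)
  n <- nrow(A)
  pos <- sample.int(n * n, 1L)
  i <- ((pos - 1L) %% n) + 1L
  j <- ((pos - 1L) %/% n) + 1L
  from <- A[i, j]
  to <- sample(setdiff(c(-1L, 0L, 1L), from), 1L)
  A[i, j] <- to
  list(matrix = A, i = i, j = j, from = from, to = to)
}

# condition helpers -----------------------------------------------------

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = "tbn_invalid_input"))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = "tbn_degenerate_input"))
}

stop_capacity <- function(msg) {
  stop(errorCondition(msg, class = "tbn_capacity_error"))
}

stop_multi_es <- function(msg) {
  stop(errorCondition(msg, class = "tbn_multi_es"))
}
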