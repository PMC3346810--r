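# Independent brute-force oracle, kept deliberately separate from the
# package's compiled engine: plain-R trajectory walking for attractors,
# reachability closure by boolean matrix powers for the terminal SCCs, and
# an eigenvector route to the stationary distribution.

oracle_successor <- function(A, code) {
  n <- nrow(A)
  bits <- as.integer(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
  h <- as.vector(A %*% bits)
  newbits <- ifelse(h > 0, 1L, ifelse(h < 0, 0L, bits))
  sum(newbits * 2^(0:(n - 1)))
}

oracle_attractors <- function(A) {
  n <- nrow(A)
  S <- 2^n
  succ <- vapply(0:(S - 1), function(s) oracle_successor(A, s), numeric(1))
  keys <- character(0)
  cycles <- list()
  attr_of <- integer(S)
  for (s0 in 0:(S - 1)) {
    traj <- s0
    repeat {
      nxt <- succ[traj[length(traj)] + 1]
      pos <- match(nxt, traj)
      if (!is.na(pos)) break
      traj <- c(traj, nxt)
    }
    cyc <- traj[pos:length(traj)]
    m <- which.min(cyc)
    if (m > 1) cyc <- c(cyc[m:length(cyc)], cyc[seq_len(m - 1)])
    key <- paste(cyc, collapse = "-")
    id <- match(key, keys)
    if (is.na(id)) {
      keys <- c(keys, key)
      cycles[[length(cycles) + 1]] <- cyc
      id <- length(keys)
    }
    attr_of[s0 + 1] <- id
  }
  ord <- order(vapply(cycles, `[[`, numeric(1), 1))
  list(cycles = cycles[ord], keys = keys[ord],
       attr_of = match(attr_of, ord))
}

oracle_flip_weights <- function(A, oa, lambda = 1, use_penalty = FALSE) {
  n <- nrow(A)
  nA <- length(oa$cycles)
  W <- matrix(0, nA, nA)
  for (a in seq_len(nA)) {
    for (s in oa$cycles[[a]]) {
      bits <- as.integer(bitwAnd(bitwShiftR(s, 0:(n - 1)), 1L))
      h <- as.vector(A %*% bits)
      for (g in seq_len(n)) {
        tgt <- oa$attr_of[bitwXor(s, 2^(g - 1)) + 1]
        flip_on <- bits[g] == 0L
        pen <- use_penalty && ((flip_on && h[g] < 0) || (!flip_on && h[g] > 0))
        W[a, tgt] <- W[a, tgt] + if (pen) lambda else 1
      }
    }
  }
  W
}

oracle_stationary <- function(P) {
  if (nrow(P) == 1) return(1)
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v / sum(v)
}

# list of ergodic sets: each with member attractor keys and stationary probs
oracle_es <- function(A, lambda = 1, use_penalty = FALSE) {
  oa <- oracle_attractors(A)
  nA <- length(oa$cycles)
  W <- oracle_flip_weights(A, oa, lambda, use_penalty)
  R <- (W > 0) | diag(nA) > 0
  repeat {
    R2 <- ((R %*% R) > 0) | R
    if (all(R2 == R)) break
    R <- R2
  }
  scc <- integer(nA)
  ncls <- 0
  for (a in seq_len(nA)) {
    if (scc[a] == 0) {
      ncls <- ncls + 1
      scc[R[a, ] & R[, a]] <- ncls
    }
  }
  out <- list()
  for (cc in seq_len(ncls)) {
    memb <- which(scc == cc)
    rest <- setdiff(seq_len(nA), memb)
    if (sum(W[memb, rest]) > 0) next
    P <- W[memb, memb, drop = FALSE] / rowSums(W[memb, , drop = FALSE])
    pi <- oracle_stationary(P)
    names(pi) <- oa$keys[memb]
    out[[length(out) + 1]] <- list(keys = oa$keys[memb], pi = pi,
                                   lengths = lengths(oa$cycles[memb]))
  }
  first_code <- vapply(out, function(e)
    as.numeric(strsplit(e$keys[1], "-")[[1]][1]), numeric(1))
  out[order(first_code)]
}

oracle_tv <- function(pi_a, pi_b) {
  keys <- union(names(pi_a), names(pi_b))
  pa <- ifelse(keys %in% names(pi_a), pi_a[keys], 0)
  pb <- ifelse(keys %in% names(pi_b), pi_b[keys], 0)
  pa[is.na(pa)] <- 0
  pb[is.na(pb)] <- 0
  sum(abs(pa - pb)) / 2
}

oracle_sensitivity <- function(A, lambda = 1, use_penalty = FALSE) {
  wt <- oracle_es(A, lambda, use_penalty)
  stopifnot(length(wt) == 1)
  ds <- c()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (A[i, j] == 0) next
      B <- A
      B[i, j] <- 0L
      mes <- oracle_es(B, lambda, use_penalty)
      if (length(mes) != 1) next
      ds <- c(ds, oracle_tv(wt[[1]]$pi, mes[[1]]$pi))
    }
  }
  mean(ds)
}

# a hand-picked 4-gene network with two Ergodic Sets (located by seeded
# search over random networks, then frozen here)
multi_es_fixture <- function() {
  rbind(c(0L,  1L,  0L, -1L),
        c(1L,  0L,  0L, -1L),
        c(0L,  0L, -1L,  1L),
        c(0L, -1L,  1L,  0L))
}
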