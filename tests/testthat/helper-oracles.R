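# Independent oracles, deliberately written apart from the package code:
# - brute-force enumeration of all legal profile-HMM paths
# - naive full-matrix Smith-Waterman
# - a second, loop-based MCL implementation

# enumerate every legal local path (enter at any match state on any
# residue, exit from any match state) and return max / logsum in bits
oracle_hmm <- function(h, seq) {
  x <- pestiscan:::aa_indices(seq, x_code = 0L)
  K <- h$n_match
  bg <- h$background
  odM <- function(k, r) if (r == 0L) 1 else h$match_emissions[k, r] / bg[r]
  odI <- function(k, r) if (r == 0L) 1 else h$insert_emissions[k, r] / bg[r]
  tr <- h$transitions
  L <- length(x)
  scores <- numeric(0)
  rec <- function(state, k, i, acc) {
    if (state == "M")
      scores[[length(scores) + 1L]] <<- acc + log2(1 / K)   # exit
    if (k >= K) return(invisible())
    if (state == "M") {
      if (i <= L) {
        rec("M", k + 1L, i + 1L, acc + log2(tr[k, "MM"]) +
              log2(odM(k + 1L, x[i])))
        rec("I", k, i + 1L, acc + log2(tr[k, "MI"]) + log2(odI(k, x[i])))
      }
      rec("D", k + 1L, i, acc + log2(tr[k, "MD"]))
    } else if (state == "I") {
      if (i <= L) {
        rec("M", k + 1L, i + 1L, acc + log2(tr[k, "IM"]) +
              log2(odM(k + 1L, x[i])))
        rec("I", k, i + 1L, acc + log2(tr[k, "II"]) + log2(odI(k, x[i])))
      }
    } else {
      if (i <= L)
        rec("M", k + 1L, i + 1L, acc + log2(tr[k, "DM"]) +
              log2(odM(k + 1L, x[i])))
      rec("D", k + 1L, i, acc + log2(tr[k, "DD"]))
    }
  }
  for (k1 in seq_len(K))
    for (i1 in seq_len(L))
      rec("M", k1, i1 + 1L, log2(1 / K) + log2(odM(k1, x[i1])))
  scores <- unlist(scores)
  list(viterbi = max(scores), forward = log2(sum(2 ^ scores)))
}

# construct a random (but valid) profile HMM directly
make_test_hmm <- function(K, seed, background = rep(1 / 20, 20),
                          concentrated = FALSE) {
  set.seed(seed)
  rdist <- function(n, alpha = 1) {
    g <- matrix(stats::rgamma(n * 20L, alpha), n, 20L)
    sweep(g, 1L, rowSums(g), "/")
  }
  me <- rdist(K, if (concentrated) 0.2 else 1)
  ie <- rdist(K)
  colnames(me) <- colnames(ie) <- pestiscan::AA20
  tr <- matrix(0, max(K - 1L, 0L), 7L,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                       "DM", "DD")))
  if (K > 1L) {
    for (k in seq_len(K - 1L)) {
      a <- stats::rgamma(3L, 1); tr[k, 1:3] <- a / sum(a)
      b <- stats::rgamma(2L, 1); tr[k, 4:5] <- b / sum(b)
      d <- stats::rgamma(2L, 1); tr[k, 6:7] <- d / sum(d)
    }
  }
  structure(list(name = sprintf("test_K%d_s%d", K, seed),
                 group_label = "test", n_match = K,
                 match_emissions = me, insert_emissions = ie,
                 transitions = tr,
                 background = setNames(background / sum(background),
                                       pestiscan::AA20),
                 gathering_cutoff = NULL, source_size = 1L,
                 consensus = paste(pestiscan::AA20[
                   max.col(me, ties.method = "first")], collapse = ""),
                 match_map = seq_len(K),
                 score_basis = "full_sequence_forward_bits"),
            class = "profile_hmm")
}

# naive quadratic-space Smith-Waterman, full matrices
naive_sw <- function(a, b, S = pestiscan:::blosum62(with_x = TRUE),
                     open = 10, ext = 1) {
  ai <- pestiscan:::aa_indices(a, x_code = 21L)
  bi <- pestiscan:::aa_indices(b, x_code = 21L)
  n <- length(ai); m <- length(bi)
  M <- X <- Y <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      M[i, j] <- S[ai[i - 1L], bi[j - 1L]] +
        max(0, M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] - open, X[i - 1L, j] - ext)
      Y[i, j] <- max(M[i, j - 1L] - open, Y[i, j - 1L] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# second MCL implementation: explicit loops, row-major normalisation of
# the transposed matrix, component extraction by label propagation
oracle_mcl <- function(nodes, edges, inflation = 2, iters = 100) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- edges$weight[r]
    A[edges$to[r], edges$from[r]] <- edges$weight[r]
  }
  for (v in seq_len(n)) {
    mx <- max(A[, v])
    A[v, v] <- if (mx > 0) mx else 1
  }
  # column-normalise by hand
  for (v in seq_len(n)) A[, v] <- A[, v] / sum(A[, v])
  for (it in seq_len(iters)) {
    B <- matrix(0, n, n)
    for (i in seq_len(n))
      for (j in seq_len(n))
        B[i, j] <- sum(A[i, ] * A[, j])
    B <- B ^ inflation
    for (v in seq_len(n)) B[, v] <- B[, v] / sum(B[, v])
    if (max(abs(B - A)) < 1e-7) { A <- B; break }
    A <- B
  }
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n))
      for (j in seq_len(n))
        if ((A[i, j] > 1e-6 || A[j, i] > 1e-6) && lab[j] != lab[i]) {
          nl <- min(lab[i], lab[j]); lab[i] <- nl; lab[j] <- nl
          changed <- TRUE
        }
    if (!changed) break
  }
  unname(lapply(split(nodes, lab), sort))
}

# canonical form of a partition for comparison
canon_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, "", 1L))]
}

# small deterministic protein set helper
tiny_records <- function(...) {
  v <- c(...)
  data.frame(id = names(v), sequence = unname(v), source_tag = "",
             stringsAsFactors = FALSE)
}
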