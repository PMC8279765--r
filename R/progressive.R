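# Built-in progressive multiple aligner: UPGMA guide tree from pairwise
# Smith-Waterman distances, profile-profile merging with sum-of-pairs
# BLOSUM62 scoring and affine gaps (free end gaps). A stand-in for an
# external aligner; any externally produced alignment can be supplied to
# the downstream steps instead.

# residue frequency profile of an alignment block: 20 x L, gaps excluded
profile_freqs <- function(rows) {
  ch <- do.call(rbind, strsplit(toupper(rows), "", fixed = FALSE))
  ch[ch == "B"] <- "D"; ch[ch == "Z"] <- "E"; ch[ch == "U"] <- "C"
  L <- ncol(ch)
  P <- matrix(0, 20L, L, dimnames = list(AA20, NULL))
  for (a in seq_along(AA20))
    P[a, ] <- colSums(ch == AA20[a])
  nz <- colSums(P)
  P[, nz > 0] <- sweep(P[, nz > 0, drop = FALSE], 2L, nz[nz > 0], "/")
  P
}

merge_blocks <- function(rows_a, rows_b, sub20, gap_open, gap_ext) {
  Pa <- profile_freqs(rows_a)
  Pb <- profile_freqs(rows_b)
  S <- t(Pa) %*% sub20 %*% Pb
  res <- nw_profile_cpp(S, gap_open, gap_ext, TRUE)
  expand <- function(rows, pathcol) {
    ch <- do.call(rbind, strsplit(rows, "", fixed = FALSE))
    out <- matrix("-", nrow(ch), length(pathcol))
    out[, pathcol > 0L] <- ch[, pathcol[pathcol > 0L], drop = FALSE]
    apply(out, 1L, paste, collapse = "")
  }
  c(expand(rows_a, res$a), expand(rows_b, res$b))
}

#' Progressive multiple alignment
#'
#' @param seqs anything [as_seq_records()] accepts (>= 1 sequence)
#' @param gap_open,gap_ext affine gap penalties for profile merging
#' @return a [msa()] in the input row order
#' @export
align_progressive <- function(seqs, gap_open = 10, gap_ext = 1) {
  r <- as_seq_records(seqs)
  r$sequence <- vapply(r$sequence, clean_protein, "")
  n <- nrow(r)
  if (n == 1L) return(msa(setNames(r$sequence, r$id)))
  sub21 <- blosum62(with_x = TRUE)
  sub20 <- blosum62(FALSE)
  idx <- lapply(r$sequence, aa_indices, x_code = 21L)
  # guide distances: 1 - S(a,b) / min(S(a,a), S(b,b))
  self <- vapply(idx, function(v) sw_score_cpp(v, v, sub21, gap_open, gap_ext),
                 0)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      s <- sw_score_cpp(idx[[i]], idx[[j]], sub21, gap_open, gap_ext)
      d <- 1 - s / max(min(self[i], self[j]), 1e-9)
      D[i, j] <- D[j, i] <- min(max(d, 0), 1)
    }
  hc <- hclust(as.dist(D), method = "average")   # UPGMA
  blocks <- lapply(seq_len(n), function(i)
    list(rows = r$sequence[i], ids = r$id[i]))
  merged <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    pick <- function(k) if (k < 0L) blocks[[-k]] else merged[[k]]
    a <- pick(hc$merge[step, 1L])
    b <- pick(hc$merge[step, 2L])
    merged[[step]] <- list(
      rows = merge_blocks(a$rows, b$rows, sub20, gap_open, gap_ext),
      ids = c(a$ids, b$ids))
  }
  final <- merged[[n - 1L]]
  o <- match(r$id, final$ids)
  msa(final$rows[o], r$id)
}
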