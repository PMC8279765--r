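# Amino-acid alphabet, background frequencies and substitution matrices.

#' The 20-letter amino-acid alphabet, alphabetical one-letter order
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Swiss-Prot-style residue frequencies (release-stable rounded values),
# normalised on access.
.AA_BACKGROUND <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0664, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292)

#' Background amino-acid frequencies
#'
#' Swiss-Prot-style residue frequencies used as the null model for
#' log-odds scoring and as emission pseudocount weights.
#'
#' @return Named numeric vector over [AA20], summing to 1.
#' @export
aa_background <- function() {
  b <- .AA_BACKGROUND[AA20]
  b / sum(b)
}

# cached BLOSUM62 (from Biostrings), subset to AA20 (+ X for pairwise use)
.pkg_env <- new.env(parent = emptyenv())

blosum62 <- function(with_x = FALSE) {
  key <- if (with_x) "b62x" else "b62"
  if (is.null(.pkg_env[[key]])) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ab <- if (with_x) c(AA20, "X") else AA20
    .pkg_env[[key]] <- e$BLOSUM62[ab, ab]
  }
  .pkg_env[[key]]
}

# Map a protein string to residue indices.
# Ambiguity handling: B -> D, Z -> E, U -> C; X -> x_code (0 = "score as
# background" for HMM scoring, 21 = BLOSUM62 X column for pairwise
# alignment); '*' terminates the sequence. Anything else is an error.
aa_indices <- function(seq, x_code = 0L, what = "sequence") {
  s <- toupper(seq)
  star <- regexpr("*", s, fixed = TRUE)
  if (star > 0L) s <- substr(s, 1L, star - 1L)
  if (nchar(s) == 0L) stop(what, " is empty (or starts with '*')")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ch[ch == "B"] <- "D"; ch[ch == "Z"] <- "E"; ch[ch == "U"] <- "C"
  idx <- match(ch, AA20)
  isx <- ch == "X"
  idx[isx] <- x_code
  bad <- which(is.na(idx))
  if (length(bad) > 0L)
    stop("invalid residue '", ch[bad[1]], "' at position ", bad[1],
         " of ", what)
  as.integer(idx)
}

# sanitised uppercase protein string (ambiguities mapped, '*' truncated)
clean_protein <- function(seq, what = "sequence") {
  idx <- aa_indices(seq, x_code = 0L, what = what)
  out <- character(length(idx))
  out[idx > 0L] <- AA20[idx[idx > 0L]]
  out[idx == 0L] <- "X"
  paste(out, collapse = "")
}
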