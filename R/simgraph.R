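# All-vs-all Smith-Waterman similarity graph.

#' Pairwise local alignment score
#'
#' Smith-Waterman with affine gaps; a gap of length g costs
#' `gap_open + (g - 1) * gap_ext`.
#'
#' @param a,b protein sequence strings
#' @param matrix substitution matrix over `c(AA20, "X")` rows/columns
#' @param gap_open,gap_ext gap penalties (positive numbers)
#' @return best local score (>= 0)
#' @export
sw_score <- function(a, b, matrix = blosum62(with_x = TRUE),
                     gap_open = 10, gap_ext = 1) {
  ai <- aa_indices(a, x_code = 21L, what = "sequence a")
  bi <- aa_indices(b, x_code = 21L, what = "sequence b")
  sw_score_cpp(ai, bi, matrix, gap_open, gap_ext)
}

#' Build the all-vs-all similarity graph
#'
#' Edge weight is the raw Smith-Waterman score (BLOSUM62, gap open 10 /
#' extend 1 by default) for every unordered pair at or above `floor`;
#' pairs below the floor get no edge.
#'
#' @param reps representative sequences ([as_seq_records()])
#' @param floor minimal score for an edge (default 50)
#' @param matrix,gap_open,gap_ext see [sw_score()]
#' @return object of class `similarity_graph`: `nodes` (ids) and `edges`
#'   (data.frame from, to, weight)
#' @export
similarity_graph <- function(reps, floor = 50,
                             matrix = blosum62(with_x = TRUE),
                             gap_open = 10, gap_ext = 1) {
  r <- as_seq_records(reps)
  if (nrow(r) < 2L) stop("need at least two representatives")
  r <- r[order(r$id), , drop = FALSE]
  idx <- lapply(r$sequence, aa_indices, x_code = 21L)
  n <- nrow(r)
  from <- character(0); to <- character(0); wt <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sw_score_cpp(idx[[i]], idx[[j]], matrix, gap_open, gap_ext)
      if (s >= floor) {
        from <- c(from, r$id[i]); to <- c(to, r$id[j]); wt <- c(wt, s)
      }
    }
  }
  structure(list(nodes = r$id,
                 edges = data.frame(from = from, to = to, weight = wt,
                                    stringsAsFactors = FALSE)),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("Similarity graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
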