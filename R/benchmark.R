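# Sensitivity/specificity benchmark harness over labelled sequence sets.

#' Benchmark a model collection on labelled positive/negative sets
#'
#' Scans both sets; a positive counts as detected iff any model reports
#' it above its gathering cutoff, and a negative counts as a false
#' positive under the same rule. Per-group counts use the positives'
#' group labels when provided.
#'
#' @param collection named list of `profile_hmm` with cutoffs set
#' @param positives,negatives labelled sequence sets (non-empty, disjoint
#'   ids)
#' @param groups optional named character: positive id -> group label
#' @param use_cutoff gate on gathering cutoffs (default TRUE)
#' @return object of class `benchmark_report`: `sensitivity`,
#'   `specificity`, `per_group` (data.frame), plus raw counts
#' @export
run_benchmark <- function(collection, positives, negatives,
                          groups = NULL, use_cutoff = TRUE) {
  pos <- as_seq_records(positives)
  neg <- as_seq_records(negatives)
  if (nrow(pos) == 0L || nrow(neg) == 0L)
    stop("positive and negative sets must both be non-empty")
  both <- intersect(pos$id, neg$id)
  if (length(both))
    stop("sequence(s) present in both labelled sets: ",
         paste(utils::head(both, 5L), collapse = ", "))
  detected_ids <- function(recs) {
    h <- scan_proteins(recs, collection, use_cutoff = FALSE)
    unique(h$query_id[h$above_cutoff])
  }
  pos_hit <- detected_ids(pos)
  neg_hit <- detected_ids(neg)
  grp <- if (is.null(groups)) setNames(rep("all", nrow(pos)), pos$id)
         else groups[pos$id]
  grp[is.na(grp) | !nzchar(grp)] <- "ungrouped"
  per_group <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    ids <- pos$id[grp == g]
    data.frame(group = g, positives_total = length(ids),
               positives_detected = sum(ids %in% pos_hit),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    positives_total = nrow(pos),
    positives_detected = length(pos_hit),
    negatives_total = nrow(neg),
    negatives_above_cutoff = length(neg_hit),
    false_positive_ids = neg_hit,
    sensitivity = length(pos_hit) / nrow(pos),
    specificity = 1 - length(neg_hit) / nrow(neg),
    per_group = per_group), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark: sensitivity %.3f (%d/%d), specificity %.3f (%d FP/%d)\n",
              x$sensitivity, x$positives_detected, x$positives_total,
              x$specificity, x$negatives_above_cutoff, x$negatives_total))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}
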