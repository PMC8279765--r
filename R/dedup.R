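# Redundancy removal at 100% identity (exact duplicates and exact
# full-length substrings collapse onto the longest member).

#' Remove redundant sequences at 100% identity
#'
#' Sequences that are exact duplicates of, or exact full-length substrings
#' of, a longer sequence share a cluster; the cluster representative is the
#' longest member, ties broken lexicographically by id.
#'
#' @param seqs anything [as_seq_records()] accepts
#' @return list with `clusters` (a `cluster_set`: list of id vectors plus
#'   `singletons`) and `representatives` (sequence-record data.frame)
#' @export
deduplicate <- function(seqs) {
  r <- as_seq_records(seqs)
  if (nrow(r) < 1L) stop("need at least one sequence")
  ord <- order(-nchar(r$sequence), r$id)
  r <- r[ord, , drop = FALSE]
  rep_idx <- integer(0)
  member_of <- integer(nrow(r))
  for (i in seq_len(nrow(r))) {
    hit <- 0L
    for (j in rep_idx) {
      if (grepl(r$sequence[i], r$sequence[j], fixed = TRUE)) { hit <- j; break }
    }
    if (hit == 0L) { rep_idx <- c(rep_idx, i); member_of[i] <- i }
    else member_of[i] <- hit
  }
  clusters <- lapply(rep_idx, function(j) sort(r$id[member_of == j]))
  # deterministic cluster order: by representative id
  o <- order(r$id[rep_idx])
  clusters <- clusters[o]
  reps <- r[rep_idx[o], , drop = FALSE]
  rownames(reps) <- NULL
  list(clusters = cluster_set(clusters),
       representatives = reps)
}

#' Construct a cluster set
#'
#' A partition of sequence ids: every id appears in exactly one cluster;
#' `singletons` lists the ids of one-member clusters.
#'
#' @param clusters list of character vectors of ids
#' @return object of class `cluster_set`
#' @export
cluster_set <- function(clusters) {
  ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("clusters do not partition the ids: duplicated ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(clusters = lapply(clusters, sort),
                 singletons = sort(ids[ids %in% unlist(
                   clusters[lengths(clusters) == 1L])])),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d clusters (%d singletons), %d ids\n",
              length(x$clusters), length(x$singletons),
              length(unlist(x$clusters))))
  invisible(x)
}
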