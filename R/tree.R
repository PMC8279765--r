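# Nearest-neighbour trees for hits: profile-alignment identity distances,
# neighbour joining, Newick serialisation.

# pairwise fractional identity between two rows of a profile alignment:
# identical residue columns / columns where either row has a residue
aligned_identity <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  occ <- ca != "-" | cb != "-"
  if (!any(occ)) return(0)
  sum(ca == cb & ca != "-") / sum(occ)
}

#' Build the nearest-neighbour tree for a hit
#'
#' The query and the members of the hit's protein group are aligned to
#' the hit's model ([align_to_profile()]); distance is 1 minus the
#' fractional identity of the aligned rows. The `k` nearest members
#' (clamped to the group size) join the query in a neighbour-joining
#' tree; negative branch lengths are clamped to 0.
#'
#' @param query_id,query_seq the hit's query
#' @param model the `profile_hmm` the hit matched
#' @param group_members sequence records of the model's protein group
#' @param k number of nearest members (default 10)
#' @return object of class `neighbor_tree`: `leaves`, `newick`,
#'   `distances` (named per-member distance to the query), `tree`
#'   (an `ape::phylo`, NULL for the 2-leaf case)
#' @export
neighbor_tree <- function(query_id, query_seq, model, group_members,
                          k = 10L) {
  if (k < 1L) stop("k must be >= 1")
  g <- as_seq_records(group_members)
  if (nrow(g) == 0L) stop("group has no members")
  g <- g[g$id != query_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("group has no members besides the query")
  all_rec <- rbind(data.frame(id = query_id, sequence = query_seq,
                              source_tag = "", stringsAsFactors = FALSE),
                   g)
  aln <- align_to_profile(model, all_rec, min_bits = -Inf)
  qrow <- aln$rows[match(query_id, aln$names)]
  ids <- setdiff(aln$names, query_id)
  dq <- vapply(ids, function(id)
    1 - aligned_identity(qrow, aln$rows[match(id, aln$names)]), 0)
  names(dq) <- ids
  sel <- ids[order(dq[ids], ids)][seq_len(min(k, length(ids)))]
  leaves <- c(query_id, sel)
  n <- length(leaves)
  D <- matrix(0, n, n, dimnames = list(leaves, leaves))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      d <- 1 - aligned_identity(aln$rows[match(leaves[i], aln$names)],
                                aln$rows[match(leaves[j], aln$names)])
      D[i, j] <- D[j, i] <- d
    }
  if (n >= 3L) {
    tr <- ape::nj(as.dist(D))
    tr$edge.length[tr$edge.length < 0] <- 0
    newick <- ape::write.tree(tr)
  } else {
    tr <- NULL
    newick <- sprintf("(%s:%.6f,%s:%.6f);", leaves[1], D[1, 2] / 2,
                      leaves[2], D[1, 2] / 2)
  }
  structure(list(query_id = query_id, model_name = model$name,
                 leaves = leaves, newick = newick,
                 distances = dq[sel], tree = tr),
            class = "neighbor_tree")
}

#' @export
print.neighbor_tree <- function(x, ...) {
  cat(sprintf("Neighbour tree for %s (model %s): %d leaves\n",
              x$query_id, x$model_name, length(x$leaves)))
  cat(" ", x$newick, "\n")
  invisible(x)
}
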