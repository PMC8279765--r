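# Native Markov clustering (MCL) of a weighted similarity graph.

#' Markov clustering of a similarity graph
#'
#' Implements MCL directly: self-loops are added (weight = the node's
#' maximum incident edge weight, 1 for isolated nodes), the matrix is
#' column-normalised, then expansion (matrix squaring) alternates with
#' inflation (elementwise power, column renormalisation) until the maximum
#' elementwise change drops below `tol`. Clusters are the weakly connected
#' components of the non-zero structure of the limit matrix.
#'
#' @param graph a [similarity_graph()]
#' @param inflation inflation exponent (> 1, default 2)
#' @param tol convergence threshold on the max elementwise change
#' @param max_iter iteration cap; non-convergence is an error reporting
#'   the residual
#' @param prune entries below this are zeroed each iteration (numerical
#'   hygiene; 0 disables)
#' @return a [cluster_set()]; attributes `iterations` and
#'   `stochastic_dev` (max |column sum - 1| observed after any
#'   normalisation step) record the run
#' @export
mcl_cluster <- function(graph, inflation = 2.0, tol = 1e-6,
                        max_iter = 200L, prune = 1e-12) {
  stopifnot(inherits(graph, "similarity_graph"), inflation > 1)
  ids <- sort(graph$nodes)
  n <- length(ids)
  if (n < 1L) stop("graph has no nodes")
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- graph$edges
  if (nrow(e) > 0L) {
    fi <- match(e$from, ids); ti <- match(e$to, ids)
    if (any(fi == ti)) stop("self-loops are not allowed in the input graph")
    M[cbind(fi, ti)] <- e$weight
    M[cbind(ti, fi)] <- e$weight
  }
  loop <- apply(M, 2L, max)
  loop[loop <= 0] <- 1
  diag(M) <- loop
  colnorm <- function(A) sweep(A, 2L, colSums(A), "/")
  M <- colnorm(M)
  dev <- max(abs(colSums(M) - 1))
  it <- 0L
  repeat {
    it <- it + 1L
    M2 <- M %*% M                       # expansion
    M2 <- M2 ^ inflation                # inflation
    M2 <- colnorm(M2)
    if (prune > 0) {
      M2[M2 < prune] <- 0
      M2 <- colnorm(M2)
    }
    dev <- max(dev, abs(colSums(M2) - 1))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
    if (it >= max_iter)
      stop(sprintf("MCL did not converge in %d iterations (residual %.3g)",
                   max_iter, delta))
  }
  # clusters: weakly connected components of the limit structure
  adj <- (M > sqrt(.Machine$double.eps)) | t(M > sqrt(.Machine$double.eps))
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  clusters <- split(ids, comp)
  clusters <- clusters[order(vapply(clusters, min, ""))]
  cs <- cluster_set(unname(clusters))
  attr(cs, "iterations") <- it
  attr(cs, "stochastic_dev") <- dev
  cs
}
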