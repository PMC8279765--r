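# Pairwise identity blocks between context regions: exact k-mer seeds on
# shared diagonals, run-merged and extended ungapped with an X-drop.
# A seeded-chaining stand-in for a BLASTn comparison; inverted matches are
# found against the reverse complement. Substitution-only homology is
# recovered as single blocks; indel-containing homology splits across
# diagonals (documented limitation).

kmer_positions <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(list())
  starts <- seq_len(L - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", km)
  split(starts[ok], km[ok])
}

# ungapped X-drop extension; returns new (a0, b0, len) 0-based
extend_xdrop <- function(ca, cb, a0, b0, len, xdrop,
                         match = 1, mismatch = -2) {
  la <- length(ca); lb <- length(cb)
  # right
  best <- 0; cur <- 0; best_ext <- 0L; i <- a0 + len + 1L; j <- b0 + len + 1L
  ext <- 0L
  while (i <= la && j <= lb) {
    cur <- cur + if (ca[i] == cb[j]) match else mismatch
    ext <- ext + 1L
    if (cur > best) { best <- cur; best_ext <- ext }
    if (cur < best - xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  len <- len + best_ext
  # left
  best <- 0; cur <- 0; best_ext <- 0L; i <- a0; j <- b0
  ext <- 0L
  while (i >= 1L && j >= 1L) {
    cur <- cur + if (ca[i] == cb[j]) match else mismatch
    ext <- ext + 1L
    if (cur > best) { best <- cur; best_ext <- ext }
    if (cur < best - xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  c(a0 - best_ext, b0 - best_ext, len + best_ext)
}

blocks_one_orientation <- function(sa, sb, k, xdrop, chain_gap) {
  idx <- kmer_positions(sa, k)
  Lb <- nchar(sb)
  if (Lb < k || length(idx) == 0L) return(NULL)
  startsb <- seq_len(Lb - k + 1L)
  kmb <- substring(sb, startsb, startsb + k - 1L)
  seeds_a <- integer(0); seeds_b <- integer(0)
  hit <- kmb %in% names(idx)
  for (K in which(hit)) {
    pa <- idx[[kmb[K]]]
    seeds_a <- c(seeds_a, pa)
    seeds_b <- c(seeds_b, rep(startsb[K], length(pa)))
  }
  if (!length(seeds_a)) return(NULL)
  diag <- seeds_a - seeds_b
  out <- list()
  ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
  for (d in sort(unique(diag))) {
    pa <- sort(seeds_a[diag == d])
    # merge seed runs separated by <= chain_gap
    brk <- c(TRUE, diff(pa) > chain_gap)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      p <- pa[grp == g]
      a0 <- p[1] - 1L                      # 0-based
      len <- p[length(p)] + k - 1L - a0
      b0 <- a0 - d
      e <- extend_xdrop(ca, cb, a0, b0, len, xdrop)
      out[[length(out) + 1L]] <- c(a0 = e[1], b0 = e[2], len = e[3])
    }
  }
  m <- unique(do.call(rbind, out))
  ident <- vapply(seq_len(nrow(m)), function(i) {
    ia <- (m[i, "a0"] + 1L):(m[i, "a0"] + m[i, "len"])
    100 * mean(ca[ia] == cb[ia - m[i, "a0"] + m[i, "b0"]])
  }, 0)
  data.frame(a0 = m[, "a0"], b0 = m[, "b0"], len = m[, "len"],
             identity = ident)
}

compare_pair <- function(ra, rb, k, xdrop, chain_gap, min_block,
                         min_identity) {
  sa <- toupper(ra$sequence); sb <- toupper(rb$sequence)
  if (nchar(sa) < k || nchar(sb) < k) {
    warning("region shorter than k = ", k, "; pair ", ra$region_id, " / ",
            rb$region_id, " skipped")
    return(NULL)
  }
  res <- list()
  fw <- blocks_one_orientation(sa, sb, k, xdrop, chain_gap)
  if (!is.null(fw) && nrow(fw)) {
    fw$orientation <- "same"
    fw$b_start <- fw$b0; fw$b_end <- fw$b0 + fw$len
    res[[length(res) + 1L]] <- fw
  }
  rc <- blocks_one_orientation(sa, revcomp_dna(sb), k, xdrop, chain_gap)
  if (!is.null(rc) && nrow(rc)) {
    rc$orientation <- "inverted"
    Lb <- nchar(sb)
    rc$b_start <- Lb - (rc$b0 + rc$len)
    rc$b_end <- Lb - rc$b0
    res[[length(res) + 1L]] <- rc
  }
  if (!length(res)) return(NULL)
  df <- do.call(rbind, res)
  df <- df[df$len >= min_block & df$identity >= min_identity, ,
           drop = FALSE]
  if (nrow(df) == 0L) return(NULL)
  # non-overlap on region_a: greedy by identity-weighted length
  df <- df[order(-(df$len * df$identity), df$a0), , drop = FALSE]
  kept <- logical(nrow(df))
  tol <- 10L
  for (i in seq_len(nrow(df))) {
    ov <- FALSE
    for (j in which(kept)) {
      o <- min(df$a0[i] + df$len[i], df$a0[j] + df$len[j]) -
        max(df$a0[i], df$a0[j])
      if (o > tol) { ov <- TRUE; break }
    }
    kept[i] <- !ov
  }
  df <- df[kept, , drop = FALSE]
  data.frame(region_a = ra$region_id, a_start = df$a0,
             a_end = df$a0 + df$len, region_b = rb$region_id,
             b_start = df$b_start, b_end = df$b_end,
             pct_identity = df$identity, orientation = df$orientation,
             stringsAsFactors = FALSE)
}

#' Identity blocks between context regions
#'
#' For each consecutive pair in display order (or all pairs), exact
#' k-mer seeds are grouped per diagonal, merged into runs, extended
#' ungapped with an X-drop and reported as blocks filtered by length and
#' percent identity; matches against the reverse complement are flagged
#' `inverted`. Overlapping blocks on the first region are resolved
#' greedily (beyond a 10 bp tolerance).
#'
#' @param regions list of `context_region` (>= 2) in display order
#' @param min_block minimal block length in bp (default 100)
#' @param min_identity reporting threshold in percent (default 60)
#' @param k seed length (default 12)
#' @param xdrop ungapped extension X-drop score (default 20)
#' @param chain_gap max distance between same-diagonal seeds merged into
#'   one run
#' @param all_pairs compare every pair instead of consecutive ones
#' @return data.frame: region_a, a_start, a_end, region_b, b_start,
#'   b_end, pct_identity, orientation (0-based half-open; see
#'   [write_blocks()] for the 1-based TSV)
#' @export
compare_regions <- function(regions, min_block = 100L, min_identity = 60,
                            k = 12L, xdrop = 20, chain_gap = 100L,
                            all_pairs = FALSE) {
  stopifnot(length(regions) >= 2L)
  pairs <- if (all_pairs)
    utils::combn(length(regions), 2L, simplify = FALSE)
  else lapply(seq_len(length(regions) - 1L), function(i) c(i, i + 1L))
  out <- list()
  for (p in pairs) {
    b <- compare_pair(regions[[p[1]]], regions[[p[2]]], k, xdrop,
                      chain_gap, min_block, min_identity)
    if (!is.null(b)) out[[length(out) + 1L]] <- b
  }
  if (!length(out))
    return(data.frame(region_a = character(0), a_start = integer(0),
                      a_end = integer(0), region_b = character(0),
                      b_start = integer(0), b_end = integer(0),
                      pct_identity = numeric(0),
                      orientation = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$region_a, df$a_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write comparison blocks as TSV (1-based inclusive coordinates)
#' @param blocks output of [compare_regions()]
#' @param path output file
#' @param params named list echoed into the header comment
#' @export
write_blocks <- function(blocks, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(paste0("# ", paste(names(params), unlist(params),
                                  sep = "=", collapse = " ")), con)
  out <- blocks
  out$a_start <- out$a_start + 1L
  out$b_start <- out$b_start + 1L
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
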