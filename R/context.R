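# Genetic-environment extraction: sequence windows around genomic hits,
# with carried-over annotations and uniform ORF re-annotation.

#' Extract the flanking region around a genomic hit
#'
#' Takes up to `flank` bp on each side of the hit gene (default 5000).
#' On linear records the window is clipped at the ends and the truncation
#' flags are set; on circular records the flanks wrap across the origin
#' and the region is linearised with the anchor kept contiguous.
#'
#' @param genome GenBank file path or list of `genbank_record`
#' @param hit one row of a [scan_genome()] hit table
#' @param flank bp on each side (default 5000)
#' @return object of class `context_region`: `region_id`, `record_id`,
#'   `region_interval` (0-based half-open on the source), `sequence`,
#'   `features` (data.frame start/end 0-based half-open region-relative,
#'   strand, kind, label), `anchor_interval` (region-relative),
#'   `truncated_left`/`truncated_right`, `wrapped`
#' @export
extract_flanks <- function(genome, hit, flank = 5000L) {
  if (is.character(genome)) genome <- read_genbank(genome)
  if (inherits(genome, "genbank_record")) genome <- list(genome)
  if (is.na(hit$record_id) || is.na(hit$start))
    stop("hit has no genomic locus; run scan_genome() (not ",
         "scan_proteins()) to obtain genomic hits")
  recs <- setNames(genome, vapply(genome, function(r) r$name, ""))
  rec <- recs[[hit$record_id]]
  if (is.null(rec)) stop("record ", hit$record_id, " not present")
  L <- rec$length
  s0 <- hit$start
  e0 <- hit$end
  circular <- rec$topology == "circular" && L > (e0 - s0)
  if (!circular) {
    rs <- max(0L, s0 - flank)
    re <- min(L, e0 + flank)
    seqs <- substr(rec$sequence, rs + 1L, re)
    trunc_l <- (s0 - flank) < 0L
    trunc_r <- (e0 + flank) > L
    offset <- rs
    pos_of <- function(p) p - offset     # source 0-based -> region 0-based
    region_interval <- c(rs, re)
    wrapped <- FALSE
  } else {
    want_l <- min(flank, (L - (e0 - s0)) %/% 2L)
    want_r <- min(flank, L - (e0 - s0) - want_l)
    rs <- (s0 - want_l) %% L
    rlen <- (e0 - s0) + want_l + want_r
    doubled <- paste0(rec$sequence, rec$sequence)
    seqs <- substr(doubled, rs + 1L, rs + rlen)
    trunc_l <- FALSE; trunc_r <- FALSE
    offset <- rs
    pos_of <- function(p) (p - offset) %% L
    region_interval <- c(rs, (rs + rlen) %% L)
    wrapped <- TRUE
  }
  rlen <- nchar(seqs)
  anchor <- c(pos_of(s0), pos_of(s0) + (e0 - s0))
  # carry over annotated features fully inside the window
  feats <- list()
  for (f in rec$features) {
    if (f$kind %in% c("source")) next
    fs <- f$start - 1L; fe <- f$end
    a <- pos_of(fs); b <- a + (fe - fs)
    if (a >= 0L && b <= rlen) {
      lab <- if (!is.null(f$qualifiers$locus_tag)) f$qualifiers$locus_tag
             else if (!is.null(f$qualifiers$product)) f$qualifiers$product
             else f$kind
      feats[[length(feats) + 1L]] <- data.frame(
        start = a, end = b, strand = f$strand, kind = f$kind,
        label = lab, stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(start = integer(0), end = integer(0),
               strand = character(0), kind = character(0),
               label = character(0), stringsAsFactors = FALSE)
  structure(list(
    region_id = sprintf("%s_%d_%d", hit$record_id, s0 + 1L, e0),
    record_id = hit$record_id,
    region_interval = as.integer(region_interval),
    sequence = seqs,
    features = features,
    anchor_interval = as.integer(anchor),
    truncated_left = trunc_l, truncated_right = trunc_r,
    wrapped = wrapped), class = "context_region")
}

#' @export
print.context_region <- function(x, ...) {
  cat(sprintf("Context region %s: %d bp on %s [%d,%d), anchor [%d,%d), %d features\n",
              x$region_id, nchar(x$sequence), x$record_id,
              x$region_interval[1], x$region_interval[2],
              x$anchor_interval[1], x$anchor_interval[2],
              nrow(x$features)))
  invisible(x)
}

#' Uniformly re-annotate a context region
#'
#' Six-frame ORF calling over the region sequence (table 11, start codons
#' ATG/GTG/TTG, length floor `min_orf_aa`); ORFs whose span overlaps a
#' carried-over CDS by more than 80% are suppressed; remaining ORFs get
#' stable labels `<region_id>_orfNNN`.
#'
#' @param region `context_region`
#' @param min_orf_aa minimal ORF length in residues (default 50)
#' @return the region with ORF features appended
#' @export
annotate_region <- function(region, min_orf_aa = 50L) {
  stopifnot(inherits(region, "context_region"))
  orfs <- find_orfs(region$sequence, min_aa = min_orf_aa)
  cds <- region$features[region$features$kind == "CDS", , drop = FALSE]
  keep <- rep(TRUE, nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    if (nrow(cds) == 0L) break
    ov <- pmax(0L, pmin(orfs$end0[i], cds$end) -
                 pmax(orfs$start0[i], cds$start))
    if (any(ov / (orfs$end0[i] - orfs$start0[i]) > 0.8)) keep[i] <- FALSE
  }
  orfs <- orfs[keep, , drop = FALSE]
  if (nrow(orfs) > 0L) {
    region$features <- rbind(region$features, data.frame(
      start = orfs$start0, end = orfs$end0, strand = orfs$strand,
      kind = "ORF",
      label = sprintf("%s_orf%03d", region$region_id, seq_len(nrow(orfs))),
      stringsAsFactors = FALSE))
    o <- order(region$features$start, region$features$end)
    region$features <- region$features[o, , drop = FALSE]
    rownames(region$features) <- NULL
  }
  region
}

#' Write a context region as a GenBank-like flat file
#' @param region `context_region`
#' @param path output file
#' @export
write_region <- function(region, path) {
  feats <- lapply(seq_len(nrow(region$features)), function(i) {
    f <- region$features[i, ]
    list(kind = f$kind, start = f$start + 1L, end = f$end,
         strand = f$strand,
         parts = cbind(start = f$start + 1L, end = f$end),
         qualifiers = list(label = f$label))
  })
  rec <- structure(list(name = region$region_id,
                        length = nchar(region$sequence),
                        topology = "linear",
                        definition = sprintf("context of %s [%d..%d]",
                                             region$record_id,
                                             region$region_interval[1] + 1L,
                                             region$region_interval[2]),
                        sequence = region$sequence,
                        features = feats),
                   class = "genbank_record")
  write_genbank(rec, path)
}
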