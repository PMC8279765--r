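# Detection unit: scan proteins or GenBank genomes against a model
# collection and gate hits by the gathering cutoffs.

hit_frame <- function() {
  data.frame(query_id = character(0), model_name = character(0),
             group_label = character(0), bits = numeric(0),
             cutoff = numeric(0), above_cutoff = logical(0),
             rank = integer(0), span_start = integer(0),
             span_end = integer(0), record_id = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

# score one query against every model, sort by bits desc (lexicographic
# model-name tie-break), rank, and apply the cutoff switch
scan_one <- function(id, seq, collection, use_cutoff) {
  rows <- lapply(collection, function(h) {
    sr <- score_sequence(h, seq, id)
    data.frame(query_id = id, model_name = h$name,
               group_label = h$group_label, bits = sr$forward_bits,
               cutoff = if (is.null(h$gathering_cutoff)) NA_real_
                        else h$gathering_cutoff,
               above_cutoff = !is.null(h$gathering_cutoff) &&
                 sr$forward_bits >= h$gathering_cutoff,
               span_start = sr$query_span[1], span_end = sr$query_span[2],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$bits, df$model_name), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  if (use_cutoff) df[df$above_cutoff, , drop = FALSE]
  else df[df$bits > 0, , drop = FALSE]
}

#' Scan protein sequences against a model collection
#'
#' Every (query, model) pair is scored with the forward algorithm (the
#' score the gathering cutoff gates). With `use_cutoff = TRUE` only
#' above-cutoff hits are reported; with `use_cutoff = FALSE` every hit
#' with positive bits is reported and flagged via `above_cutoff`, so even
#' incomplete (sub-cutoff) matches surface for manual review.
#'
#' @param seqs anything [as_seq_records()] accepts
#' @param collection named list of `profile_hmm` (>= 1)
#' @param use_cutoff gate on gathering cutoffs (default TRUE)
#' @return `pestiscan_hits` data.frame, per query sorted by bits
#'   descending with 1-based `rank`
#' @export
scan_proteins <- function(seqs, collection, use_cutoff = TRUE) {
  if (length(collection) < 1L)
    stop("empty model collection: nothing to scan against")
  r <- as_seq_records(seqs)
  if (nrow(r) < 1L) stop("no query sequences")
  collection <- collection[order(vapply(collection, function(h) h$name, ""))]
  out <- lapply(seq_len(nrow(r)), function(i)
    scan_one(r$id[i], r$sequence[i], collection, use_cutoff))
  df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  df <- df[order(df$query_id, df$rank), , drop = FALSE]
  df$record_id <- rep(NA_character_, nrow(df))
  df$strand <- rep(NA_character_, nrow(df))
  df$start <- rep(NA_integer_, nrow(df))
  df$end <- rep(NA_integer_, nrow(df))
  rownames(df) <- NULL
  class(df) <- c("pestiscan_hits", "data.frame")
  df
}

# protein queries from one GenBank record: CDS /translation preferred,
# conceptual translation otherwise; ORF calling when no CDS annotated.
genome_queries <- function(rec, min_orf_aa = 50L) {
  cds <- Filter(function(f) f$kind == "CDS", rec$features)
  out <- list()
  if (length(cds)) {
    for (i in seq_along(cds)) {
      f <- cds[[i]]
      id <- if (!is.null(f$qualifiers$locus_tag)) f$qualifiers$locus_tag
            else sprintf("%s_cds%03d", rec$name, i)
      tr <- f$qualifiers$translation
      if (!is.null(tr)) {
        tr <- gsub("\\s", "", tr)
        span_nt <- sum(f$parts[, "end"] - f$parts[, "start"] + 1L)
        if (abs(span_nt / 3L - nchar(tr)) > 1L)
          warning("CDS ", id, ": /translation length inconsistent with ",
                  "coordinates; using the qualifier text")
        if (grepl("\\*.", tr))
          warning("CDS ", id, ": internal stop in /translation; ",
                  "trusting the qualifier")
        aa <- sub("\\*$", "", tr)
      } else {
        aa <- translate_cds(feature_dna(rec, f))
      }
      if (!nzchar(aa)) next
      out[[length(out) + 1L]] <- data.frame(
        id = id, sequence = gsub("\\*", "X", aa),
        record_id = rec$name, strand = f$strand,
        start = f$start - 1L, end = f$end,
        stringsAsFactors = FALSE)
    }
  } else {
    orfs <- find_orfs(rec$sequence, min_aa = min_orf_aa)
    for (i in seq_len(nrow(orfs))) {
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("%s_orf%03d", rec$name, i),
        sequence = orfs$aa[i], record_id = rec$name,
        strand = orfs$strand[i], start = orfs$start0[i],
        end = orfs$end0[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Scan a genome (GenBank records) against a model collection
#'
#' Protein queries come from CDS features (the `/translation` qualifier
#' when present, conceptual translation under table 11 otherwise);
#' records without CDS features are six-frame ORF-called first. Each hit
#' carries its genomic locus (record, strand, 0-based half-open
#' interval).
#'
#' @param genome path to a GenBank file or a list of `genbank_record`
#' @param collection named list of `profile_hmm`
#' @param use_cutoff gate on gathering cutoffs
#' @param min_orf_aa ORF floor for unannotated records
#' @return `pestiscan_hits` data.frame
#' @export
scan_genome <- function(genome, collection, use_cutoff = TRUE,
                        min_orf_aa = 50L) {
  if (is.character(genome)) genome <- read_genbank(genome)
  if (inherits(genome, "genbank_record")) genome <- list(genome)
  if (length(genome) < 1L) stop("no GenBank records")
  qs <- do.call(rbind, lapply(genome, genome_queries,
                              min_orf_aa = min_orf_aa))
  if (is.null(qs) || nrow(qs) == 0L) return(hit_frame())
  qs$uid <- sprintf("q%04d", seq_len(nrow(qs)))
  hits <- scan_proteins(setNames(qs$sequence, qs$uid), collection,
                        use_cutoff)
  if (nrow(hits) == 0L) {
    h <- hit_frame()
    class(h) <- c("pestiscan_hits", "data.frame")
    return(h)
  }
  m <- match(hits$query_id, qs$uid)
  hits$query_id <- qs$id[m]
  hits$record_id <- qs$record_id[m]
  hits$strand <- qs$strand[m]
  hits$start <- qs$start[m]
  hits$end <- qs$end[m]
  hits <- hits[order(hits$record_id, hits$start, hits$rank), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write hits as TSV (1-based inclusive genomic coordinates)
#' @param hits `pestiscan_hits`
#' @param path output file
#' @export
write_hits <- function(hits, path) {
  out <- as.data.frame(hits)
  out$start <- ifelse(is.na(out$start), NA_integer_, out$start + 1L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify queries from their hits
#'
#' The label of a query is the group label of its top above-cutoff model,
#' reported as `"candidate <group>"`; never a nomenclature assignment.
#'
#' @param hits `pestiscan_hits`
#' @return data.frame query_id, label
#' @export
classify_hits <- function(hits) {
  ab <- hits[hits$above_cutoff, , drop = FALSE]
  if (nrow(ab) == 0L)
    return(data.frame(query_id = character(0), label = character(0)))
  top <- ab[!duplicated(ab$query_id), , drop = FALSE]
  data.frame(query_id = top$query_id,
             label = paste("candidate",
                           ifelse(nzchar(top$group_label), top$group_label,
                                  top$model_name)),
             stringsAsFactors = FALSE)
}
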