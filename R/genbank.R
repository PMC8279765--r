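# Minimal GenBank flat-file reader/writer (no pre-installed R package
# parses GenBank). Supports multi-record files, LOCUS topology, feature
# tables with complement()/join() locations and multi-line qualifiers,
# and ORIGIN sequence blocks. Parsed coordinates stay 1-based inclusive
# (the format's convention); scanning/context code converts to 0-based
# half-open at its boundary.

parse_location <- function(loc) {
  txt <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", txt)) {
    strand <- "-"
    txt <- sub("^complement\\((.*)\\)$", "\\1", txt)
  }
  if (grepl("^(join|order)\\(", txt))
    txt <- sub("^(join|order)\\((.*)\\)$", "\\2", txt)
  if (grepl("complement", txt))   # mixed-strand joins unsupported
    return(NULL)
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$|^(\\d+)$", parts))
  starts <- integer(0); ends <- integer(0)
  for (g in m) {
    if (length(g) == 0L || !nzchar(g[1])) return(NULL)
    if (nzchar(g[2])) { starts <- c(starts, as.integer(g[2]))
                        ends <- c(ends, as.integer(g[3])) }
    else { starts <- c(starts, as.integer(g[4]))
           ends <- c(ends, as.integer(g[4])) }
  }
  list(start = min(starts), end = max(ends), strand = strand,
       parts = cbind(start = starts, end = ends))
}

#' Read a GenBank flat file
#'
#' @param path GenBank file (possibly multi-record)
#' @return list of records of class `genbank_record`: `name`, `length`,
#'   `topology`, `definition`, `sequence` (uppercase DNA) and `features`
#'   (list of: `kind`, `start`/`end` 1-based inclusive, `strand`,
#'   `parts`, `qualifiers`)
#' @export
read_genbank <- function(path) {
  ln <- sub("\r$", "", readLines(path))
  rec_end <- grep("^//", ln)
  rec_start <- c(1L, utils::head(rec_end, -1L) + 1L)
  if (!length(rec_end)) stop("no record terminator '//' found in ", path)
  records <- list()
  for (ri in seq_along(rec_end)) {
    chunk <- ln[rec_start[ri]:rec_end[ri]]
    chunk <- chunk[nzchar(trimws(chunk)) | seq_along(chunk) == 1L]
    locus_i <- grep("^LOCUS", chunk)[1]
    if (is.na(locus_i)) next
    tok <- strsplit(trimws(chunk[locus_i]), "\\s+")[[1]]
    name <- tok[2]
    len <- suppressWarnings(as.integer(tok[3]))
    topology <- if (any(tok == "circular")) "circular" else "linear"
    def_i <- grep("^DEFINITION", chunk)
    definition <- if (length(def_i)) trimws(sub("^DEFINITION", "",
                                                chunk[def_i[1]])) else ""
    # sequence
    ori_i <- grep("^ORIGIN", chunk)
    seqstr <- ""
    if (length(ori_i)) {
      body <- chunk[(ori_i[1] + 1L):(length(chunk) - 1L)]
      seqstr <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    if (is.na(len)) len <- nchar(seqstr)
    # features
    features <- list()
    fi <- grep("^FEATURES", chunk)
    if (length(fi)) {
      fend <- if (length(ori_i)) ori_i[1] - 1L else length(chunk) - 1L
      fl <- chunk[(fi[1] + 1L):fend]
      key_i <- grep("^ {5}\\S", fl)
      for (j in seq_along(key_i)) {
        from <- key_i[j]
        to <- if (j < length(key_i)) key_i[j + 1L] - 1L else length(fl)
        block <- fl[from:to]
        kind <- sub("^\\s+(\\S+).*$", "\\1", block[1])
        rest <- sub("^\\s+\\S+\\s*", "", block[1])
        qual_i <- grep("^ +/", block)
        loc_lines <- if (length(qual_i)) block[seq_len(qual_i[1] - 1L)]
                     else block
        loc <- paste(c(rest, trimws(loc_lines[-1])), collapse = "")
        ploc <- parse_location(loc)
        if (is.null(ploc)) next
        quals <- list()
        if (length(qual_i)) {
          qtxt <- trimws(block[qual_i[1]:length(block)])
          cur <- NULL
          for (q in qtxt) {
            if (startsWith(q, "/")) {
              if (!is.null(cur)) quals[[cur$k]] <- cur$v
              eq <- regexpr("=", q, fixed = TRUE)
              if (eq > 0) cur <- list(k = substr(q, 2L, eq - 1L),
                                      v = substring(q, eq + 1L))
              else cur <- list(k = substring(q, 2L), v = "")
            } else if (!is.null(cur)) {
              sep <- if (cur$k == "translation") "" else " "
              cur$v <- paste(cur$v, q, sep = sep)
            }
          }
          if (!is.null(cur)) quals[[cur$k]] <- cur$v
          quals <- lapply(quals, function(v) gsub("^\"|\"$", "", v))
        }
        features[[length(features) + 1L]] <-
          list(kind = kind, start = ploc$start, end = ploc$end,
               strand = ploc$strand, parts = ploc$parts,
               qualifiers = quals)
      }
    }
    records[[length(records) + 1L]] <- structure(
      list(name = name, length = len, topology = topology,
           definition = definition, sequence = seqstr,
           features = features),
      class = "genbank_record")
  }
  records
}

wrap_qualifier <- function(key, value, width = 58L) {
  txt <- sprintf("/%s=\"%s\"", key, value)
  out <- character(0)
  while (nchar(txt) > width) {
    out <- c(out, substr(txt, 1L, width))
    txt <- substring(txt, width + 1L)
  }
  c(out, txt)
}

#' Write GenBank records to a flat file
#'
#' @param records list of `genbank_record` (or a single one)
#' @param path output file
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "genbank_record")) records <- list(records)
  out <- character(0)
  for (rec in records) {
    out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %s   BCT",
                          rec$name, rec$length,
                          if (rec$topology == "circular") "circular"
                          else "linear  "))
    if (nzchar(rec$definition))
      out <- c(out, paste("DEFINITION ", rec$definition))
    out <- c(out, "FEATURES             Location/Qualifiers")
    feats <- rec$features
    if (!any(vapply(feats, function(f) f$kind == "source", TRUE)))
      out <- c(out, sprintf("     source          1..%d", rec$length))
    for (f in feats) {
      loc <- if (nrow(f$parts) > 1L)
        sprintf("join(%s)", paste(sprintf("%d..%d", f$parts[, "start"],
                                          f$parts[, "end"]),
                                  collapse = ","))
      else sprintf("%d..%d", f$start, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     %-15s %s", f$kind, loc))
      for (k in names(f$qualifiers))
        out <- c(out, paste0("                     ",
                             wrap_qualifier(k, f$qualifiers[[k]])))
    }
    out <- c(out, "ORIGIN")
    s <- rec$sequence
    for (off in seq(1L, nchar(s), by = 60L)) {
      chunkseq <- substr(s, off, min(off + 59L, nchar(s)))
      groups <- substring(chunkseq, seq(1L, nchar(chunkseq), 10L),
                          pmin(seq(10L, nchar(chunkseq) + 9L, 10L),
                               nchar(chunkseq)))
      out <- c(out, sprintf("%9d %s", off,
                            tolower(paste(groups, collapse = " "))))
    }
    out <- c(out, "//")
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.genbank_record <- function(x, ...) {
  cat(sprintf("GenBank record %s: %d bp, %s, %d features\n",
              x$name, x$length, x$topology, length(x$features)))
  invisible(x)
}

revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# conceptual translation, bacterial/archaeal code (table 11)
translate_cds <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, n)),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

# spliced CDS nucleotide sequence for a parsed feature
feature_dna <- function(rec, f) {
  parts <- f$parts
  seqs <- vapply(seq_len(nrow(parts)), function(i)
    substr(rec$sequence, parts[i, "start"], parts[i, "end"]), "")
  s <- paste(seqs, collapse = "")
  if (f$strand == "-") revcomp_dna(s) else s
}
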