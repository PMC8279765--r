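# Multiple-alignment container.

#' Construct a multiple sequence alignment
#'
#' Rows are equal-length aligned strings over the amino-acid alphabet plus
#' the gap symbol `-` (`.` is accepted and normalised to `-`). Lower-case
#' letters mark insert-state residues in profile alignments and are kept.
#'
#' @param rows character vector of aligned rows
#' @param names unique sequence identifiers (defaults to `names(rows)`)
#' @return object of class `pestiscan_msa`
#' @export
msa <- function(rows, names = base::names(rows)) {
  if (is.null(names)) names <- paste0("seq", seq_along(rows))
  rows <- gsub(".", "-", as.character(rows), fixed = TRUE)
  if (length(rows) < 1L) stop("alignment needs at least one row")
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length")
  if (nchar(rows[1]) < 1L) stop("alignment has zero columns")
  if (anyDuplicated(names)) stop("alignment identifiers not unique")
  ok <- grepl(paste0("^[", paste(AA20, collapse = ""),
                     "acdefghiklmnpqrstvwyXBZUxbzu-]*$"), rows)
  if (!all(ok)) {
    row <- which(!ok)[1]
    ch <- strsplit(rows[row], "")[[1]]
    bad <- which(!ch %in% c(AA20, tolower(AA20), "X", "B", "Z", "U",
                            "x", "b", "z", "u", "-"))[1]
    stop("invalid residue '", ch[bad], "' in alignment row ", row,
         " ('", names[row], "'), column ", bad)
  }
  structure(list(names = as.character(names), rows = rows),
            class = "pestiscan_msa")
}

#' @export
print.pestiscan_msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              length(x$rows), nchar(x$rows[1])))
  show <- utils::head(seq_along(x$rows), 8L)
  for (i in show)
    cat(sprintf("  %-15s %s\n", x$names[i],
                if (nchar(x$rows[i]) > 60) paste0(substr(x$rows[i], 1, 60), "...")
                else x$rows[i]))
  if (length(x$rows) > 8L) cat("  ...\n")
  invisible(x)
}

# character matrix view, uppercased, ambiguities mapped (B->D, Z->E, U->C);
# X kept as X; errors name row and column for anything else.
msa_matrix <- function(m) {
  ch <- do.call(rbind, strsplit(toupper(m$rows), "", fixed = FALSE))
  ch[ch == "."] <- "-"
  ch[ch == "B"] <- "D"; ch[ch == "Z"] <- "E"; ch[ch == "U"] <- "C"
  bad <- !(ch %in% c(AA20, "X", "-"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid residue '", ch[w[1], w[2]], "' in alignment row ", w[1],
         " ('", m$names[w[1]], "'), column ", w[2])
  }
  rownames(ch) <- m$names
  ch
}

#' Read an aligned FASTA file as an Msa
#' @param path aligned FASTA
#' @return `pestiscan_msa`
#' @export
read_msa <- function(path) {
  r <- as_seq_records(path)
  msa(setNames(r$sequence, r$id))
}

#' Write an Msa as aligned FASTA
#' @param m `pestiscan_msa`
#' @param path output file
#' @export
write_msa <- function(m, path) {
  write_fasta(data.frame(id = m$names, sequence = m$rows,
                         stringsAsFactors = FALSE), path)
}

# drop all-gap columns (used after subsetting alignments)
msa_drop_gap_cols <- function(m) {
  ch <- do.call(rbind, strsplit(m$rows, "", fixed = FALSE))
  keep <- colSums(ch != "-") > 0L
  if (!any(keep)) stop("alignment reduced to zero columns")
  msa(apply(ch[, keep, drop = FALSE], 1L, paste, collapse = ""), m$names)
}
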