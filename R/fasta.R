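# Sequence records and FASTA input/output (Biostrings-backed).

#' Coerce to a sequence-record table
#'
#' The package-wide sequence container is a plain data.frame with columns
#' `id`, `sequence` and `source_tag`. Accepts a named character vector, a
#' data.frame with at least `id`/`sequence`, an `XStringSet`, or a FASTA
#' file path.
#'
#' @param x input to coerce
#' @return data.frame with columns `id`, `sequence`, `source_tag`
#' @export
as_seq_records <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    out <- data.frame(id = as.character(x$id),
                      sequence = as.character(x$sequence),
                      source_tag = if ("source_tag" %in% names(x))
                        as.character(x$source_tag) else "",
                      stringsAsFactors = FALSE)
  } else if (methods::is(x, "XStringSet")) {
    nm <- names(x)
    id <- sub("\\s.*$", "", nm)
    tag <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
    out <- data.frame(id = id, sequence = as.character(x),
                      source_tag = tag, stringsAsFactors = FALSE)
  } else if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
             file.exists(x)) {
    return(read_fasta(x))
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("character input must be named (id -> sequence)")
    out <- data.frame(id = names(x), sequence = unname(x),
                      source_tag = "", stringsAsFactors = FALSE)
  } else {
    stop("cannot coerce to sequence records: ", class(x)[1])
  }
  if (anyDuplicated(out$id)) stop("duplicated sequence ids: ",
    paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  if (any(nchar(out$sequence) < 1L)) stop("zero-length sequence present")
  rownames(out) <- NULL
  out
}

#' Read protein sequences from FASTA
#'
#' Wrapped or unwrapped records; CRLF line endings are tolerated.
#'
#' @param path FASTA file
#' @return sequence-record data.frame (see [as_seq_records()])
#' @export
read_fasta <- function(path) {
  as_seq_records(Biostrings::readAAStringSet(path))
}

#' Write sequence records to FASTA
#'
#' @param records anything [as_seq_records()] accepts
#' @param path output file
#' @param width line-wrap width
#' @export
write_fasta <- function(records, path, width = 60L) {
  r <- as_seq_records(records)
  nm <- ifelse(nzchar(r$source_tag), paste(r$id, r$source_tag), r$id)
  x <- Biostrings::AAStringSet(setNames(r$sequence, nm))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
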