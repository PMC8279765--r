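# Six-frame ORF calling, bacterial code (table 11): start ATG/GTG/TTG,
# stop-to-stop segments, a lightweight uniform stand-in for full genome
# annotation.

ORF_STARTS <- c("ATG", "GTG", "TTG")
ORF_STOPS <- c("TAA", "TAG", "TGA")

orfs_one_strand <- function(s, min_aa) {
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    cod_start <- seq(frame + 1L, L - 2L, by = 3L)
    if (length(cod_start) == 0L) next
    codons <- substring(s, cod_start, cod_start + 2L)
    stop_i <- which(codons %in% ORF_STOPS)
    start_ok <- codons %in% ORF_STARTS
    prev <- 0L
    for (si in stop_i) {
      cand <- which(start_ok[(prev + 1L):(si - 1L)])
      if (length(cand)) {
        st <- prev + cand[1L]
        n_aa <- si - st          # codons before the stop
        if (n_aa >= min_aa) {
          out[[length(out) + 1L]] <- c(start0 = cod_start[st] - 1L,
                                       end0 = cod_start[si] + 2L)
        }
      }
      prev <- si
    }
  }
  out
}

#' Call open reading frames in six frames
#'
#' @param seq DNA string over A/C/G/T/N
#' @param min_aa minimal protein length in residues, stop excluded
#'   (default 50)
#' @return data.frame: `start0`, `end0` (0-based half-open, stop codon
#'   included), `strand`, `aa` (translation, table 11, leading residue M)
#' @export
find_orfs <- function(seq, min_aa = 50L) {
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s))
    stop("sequence contains non-IUPAC characters (expected A/C/G/T/N)")
  L <- nchar(s)
  fw <- orfs_one_strand(s, min_aa)
  rv <- orfs_one_strand(revcomp_dna(s), min_aa)
  rows <- list()
  for (o in fw)
    rows[[length(rows) + 1L]] <- data.frame(
      start0 = o[["start0"]], end0 = o[["end0"]], strand = "+",
      stringsAsFactors = FALSE)
  for (o in rv)
    rows[[length(rows) + 1L]] <- data.frame(
      start0 = L - o[["end0"]], end0 = L - o[["start0"]], strand = "-",
      stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      strand = character(0), aa = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$start0, df$end0, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df$aa <- vapply(seq_len(nrow(df)), function(i) {
    dna <- substr(s, df$start0[i] + 1L, df$end0[i])
    if (df$strand[i] == "-") dna <- revcomp_dna(dna)
    aa <- translate_cds(dna)
    paste0("M", substring(aa, 2L))   # alternative starts read as Met
  }, "")
  df
}
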