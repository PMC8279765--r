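# Viterbi and forward scoring of sequences against a profile HMM.

hmm_log_params <- function(h) {
  bg <- h$background
  list(lem = log2(sweep(h$match_emissions, 2L, bg, "/")),
       lei = log2(sweep(h$insert_emissions, 2L, bg, "/")),
       ltr = log2(h$transitions))
}

#' Score a sequence against a profile HMM
#'
#' Computes both the Viterbi (best-path) and forward (all-path) log2-odds
#' bit scores under local alignment with uniform entry/exit over match
#' states, HMMER-style: flanking residues score 0 against the background.
#' `X` scores as background, `B`/`Z`/`U` map to `D`/`E`/`C`, `*`
#' terminates the sequence.
#'
#' @param h `profile_hmm`
#' @param seq protein sequence string
#' @param name query identifier carried into the result
#' @return object of class `score_result` with fields `model_name`,
#'   `query_name`, `viterbi_bits`, `forward_bits`, `alignment`
#'   (data.frame: `query_index` 1-based or NA for deletes, `state`),
#'   `query_span` (0-based half-open)
#' @export
score_sequence <- function(h, seq, name = "query") {
  validate_profile_hmm(h)
  x <- aa_indices(seq, x_code = 0L, what = paste0("query '", name, "'"))
  p <- hmm_log_params(h)
  res <- hmm_score_cpp(p$lem, p$lei, p$ltr, x)
  path <- res$path
  aln <- data.frame(query_index = ifelse(path[, "pos"] == 0L, NA_integer_,
                                         path[, "pos"]),
                    state = paste0(c("M", "I", "D")[path[, "state"]],
                                   path[, "node"]),
                    stringsAsFactors = FALSE)
  pos <- aln$query_index[!is.na(aln$query_index)]
  span <- if (length(pos)) c(min(pos) - 1L, max(pos)) else c(0L, 0L)
  structure(list(model_name = h$name,
                 query_name = name,
                 viterbi_bits = res$viterbi_bits,
                 forward_bits = res$forward_bits,
                 alignment = aln,
                 query_span = as.integer(span)),
            class = "score_result")
}

#' @rdname score_sequence
#' @export
viterbi_score <- function(h, seq, name = "query") score_sequence(h, seq, name)

#' @rdname score_sequence
#' @export
forward_score <- function(h, seq, name = "query") score_sequence(h, seq, name)

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("%s vs %s: viterbi %.2f bits, forward %.2f bits, span [%d,%d)\n",
              x$query_name, x$model_name, x$viterbi_bits, x$forward_bits,
              x$query_span[1], x$query_span[2]))
  invisible(x)
}

#' Align sequences to a profile HMM
#'
#' Each sequence is aligned independently via its Viterbi path; match
#' states define the (upper-case) columns, insertions are rendered as
#' lower-case, gap-padded columns between match columns. Sequences whose
#' Viterbi score falls below `min_bits` are reported as unalignable and
#' excluded with a warning.
#'
#' @param h `profile_hmm`
#' @param seqs anything [as_seq_records()] accepts
#' @param min_bits alignment floor in bits (default 0)
#' @return a [msa()] of the alignable sequences
#' @export
align_to_profile <- function(h, seqs, min_bits = 0) {
  r <- as_seq_records(seqs)
  K <- h$n_match
  paths <- vector("list", nrow(r))
  keep <- logical(nrow(r))
  for (i in seq_len(nrow(r))) {
    sr <- score_sequence(h, r$sequence[i], r$id[i])
    if (sr$viterbi_bits < min_bits || nrow(sr$alignment) == 0L) next
    keep[i] <- TRUE
    paths[[i]] <- sr
  }
  if (!any(keep)) stop("no sequence aligned above the ", min_bits,
                       "-bit floor")
  if (any(!keep))
    warning("unalignable below ", min_bits, " bits, excluded: ",
            paste(r$id[!keep], collapse = ", "))
  r <- r[keep, , drop = FALSE]
  paths <- paths[keep]
  # per-sequence: residue at each match state, insert run after each node
  mat_res <- matrix("-", nrow(r), K)
  ins_runs <- matrix("", nrow(r), K)   # run after node k (1..K-1 used)
  for (i in seq_len(nrow(r))) {
    sq <- strsplit(clean_protein(r$sequence[i]), "")[[1]]
    a <- paths[[i]]$alignment
    st <- substr(a$state, 1L, 1L)
    nd <- as.integer(substring(a$state, 2L))
    for (j in seq_len(nrow(a))) {
      if (st[j] == "M") mat_res[i, nd[j]] <- sq[a$query_index[j]]
      else if (st[j] == "I")
        ins_runs[i, nd[j]] <- paste0(ins_runs[i, nd[j]],
                                     tolower(sq[a$query_index[j]]))
    }
  }
  ins_w <- apply(nchar(ins_runs), 2L, max)
  rows <- character(nrow(r))
  for (i in seq_len(nrow(r))) {
    parts <- character(0)
    for (k in seq_len(K)) {
      parts <- c(parts, mat_res[i, k])
      if (ins_w[k] > 0L)
        parts <- c(parts, formatC(ins_runs[i, k], width = -ins_w[k],
                                  flag = "-"))
    }
    rows[i] <- gsub(" ", "-", paste(parts, collapse = ""), fixed = TRUE)
  }
  msa(rows, r$id)
}
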