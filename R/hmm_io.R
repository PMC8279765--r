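# Model serialization: native plain-text format (bit-exact round trip)
# and HMMER3 ASCII export / best-effort import.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a profile HMM in the native plain-text format
#'
#' Numbers are printed with 17 significant digits so that
#' `read_model(write_model(h))` round-trips bit-exactly.
#'
#' @param h `profile_hmm`
#' @param path output file
#' @export
write_model <- function(h, path) {
  validate_profile_hmm(h)
  con <- file(path, "w")
  on.exit(close(con))
  out <- c(
    "PESTISCAN-HMM 1",
    paste("NAME", h$name),
    paste("GROUP", h$group_label),
    paste("NMATCH", h$n_match),
    paste("SOURCE_SIZE", h$source_size),
    paste("SCORE_BASIS", h$score_basis),
    paste("GA", if (is.null(h$gathering_cutoff)) "-"
          else fmt17(h$gathering_cutoff)),
    paste("CONSENSUS", h$consensus),
    paste("MAP", paste(h$match_map, collapse = " ")),
    paste("BG", paste(fmt17(h$background), collapse = " ")))
  for (k in seq_len(h$n_match))
    out <- c(out, paste("MATCH", k,
                        paste(fmt17(h$match_emissions[k, ]), collapse = " ")))
  for (k in seq_len(h$n_match))
    out <- c(out, paste("INSERT", k,
                        paste(fmt17(h$insert_emissions[k, ]), collapse = " ")))
  if (nrow(h$transitions) > 0L)
    for (k in seq_len(nrow(h$transitions)))
      out <- c(out, paste("TRANS", k,
                          paste(fmt17(h$transitions[k, ]), collapse = " ")))
  out <- c(out, "END")
  writeLines(out, con)
  invisible(path)
}

#' Read a profile HMM from the native plain-text format
#' @param path file written by [write_model()]
#' @return `profile_hmm`
#' @export
read_model <- function(path) {
  ln <- readLines(path)
  ln <- sub("\r$", "", ln)
  if (!startsWith(ln[1], "PESTISCAN-HMM"))
    stop("not a pestiscan model file: ", path)
  field <- function(key) {
    i <- grep(paste0("^", key, " "), ln)
    if (!length(i)) return(NULL)
    sub(paste0("^", key, " "), "", ln[i[1]])
  }
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  K <- as.integer(field("NMATCH"))
  gat <- field("GA")
  parse_block <- function(key, ncolumn) {
    i <- grep(paste0("^", key, " "), ln)
    m <- matrix(0, length(i), ncolumn)
    for (r in seq_along(i)) {
      v <- nums(sub(paste0("^", key, " "), "", ln[i[r]]))
      m[as.integer(v[1]), ] <- v[-1]
    }
    m
  }
  me <- parse_block("MATCH", 20L); colnames(me) <- AA20
  ie <- parse_block("INSERT", 20L); colnames(ie) <- AA20
  tr <- if (K > 1L) parse_block("TRANS", 7L) else
    matrix(0, 0L, 7L)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  h <- structure(list(
    name = field("NAME"),
    group_label = if (is.null(field("GROUP"))) "" else field("GROUP"),
    n_match = K,
    match_emissions = me,
    insert_emissions = ie,
    transitions = tr,
    background = setNames(nums(field("BG")), AA20),
    gathering_cutoff = if (identical(gat, "-")) NULL else as.numeric(gat),
    source_size = as.integer(field("SOURCE_SIZE")),
    consensus = field("CONSENSUS"),
    match_map = as.integer(nums(field("MAP"))),
    score_basis = field("SCORE_BASIS")
  ), class = "profile_hmm")
  validate_profile_hmm(h)
  h
}

#' Write a model collection directory
#'
#' One native model file per model plus an index TSV (name, group,
#' n_match, gathering cutoff, source size).
#'
#' @param models list of `profile_hmm`
#' @param dir output directory (created)
#' @param hmmer3 also write a HMMER3 ASCII export per model
#' @export
write_model_collection <- function(models, dir, hmmer3 = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(name = character(0), group = character(0),
                    n_match = integer(0), gathering_cutoff = numeric(0),
                    source_size = integer(0))
  for (h in models) {
    write_model(h, file.path(dir, paste0(h$name, ".phmm")))
    if (hmmer3) write_hmmer3(h, file.path(dir, paste0(h$name, ".hmm")))
    idx <- rbind(idx, data.frame(
      name = h$name, group = h$group_label, n_match = h$n_match,
      gathering_cutoff = if (is.null(h$gathering_cutoff)) NA_real_
                         else h$gathering_cutoff,
      source_size = h$source_size))
  }
  write.table(idx, file.path(dir, "models.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a model collection directory
#' @param dir directory written by [write_model_collection()]
#' @return named list of `profile_hmm`
#' @export
read_model_collection <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.phmm$", full.names = TRUE))
  if (!length(files)) stop("no .phmm model files in ", dir)
  models <- lapply(files, read_model)
  setNames(models, vapply(models, function(h) h$name, ""))
}

# -ln(p) with "*" for p == 0, HMMER convention
hmmer_num <- function(p) ifelse(p <= 0, "*", sprintf("%.5f", -log(p)))

#' Export a model in HMMER3 ASCII ("HMMER3/f") layout
#'
#' Interoperability export; pestiscan has no J-state/multihit machinery or
#' E-value statistics, so STATS lines are omitted and node-0 transitions
#' are uniform placeholders.
#'
#' @param h `profile_hmm`
#' @param path output file
#' @export
write_hmmer3 <- function(h, path) {
  validate_profile_hmm(h)
  K <- h$n_match
  out <- c(
    "HMMER3/f [pestiscan export]",
    sprintf("NAME  %s", h$name),
    sprintf("DESC  %s", h$group_label),
    sprintf("LENG  %d", K),
    "ALPH  amino",
    "RF    no", "MM    no", "CONS  yes", "CS    no", "MAP   yes")
  if (!is.null(h$gathering_cutoff))
    out <- c(out, sprintf("GA    %.2f %.2f;", h$gathering_cutoff,
                          h$gathering_cutoff))
  out <- c(out,
    paste0("HMM          ", paste(sprintf("%-8s", AA20), collapse = " ")),
    paste0("            ", paste(sprintf("%-8s",
      c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
      collapse = " ")),
    paste0("  COMPO   ", paste(sprintf("%-8s",
      hmmer_num(colMeans(h$match_emissions))), collapse = " ")),
    paste0("          ", paste(sprintf("%-8s", hmmer_num(h$background)),
      collapse = " ")),
    paste0("          ", paste(sprintf("%-8s",
      c(hmmer_num(c(0.99, 0.005, 0.005, 0.5, 0.5)), "0.00000", "*")),
      collapse = " ")))
  cons <- strsplit(h$consensus, "")[[1]]
  for (k in seq_len(K)) {
    if (k < K) {
      tp <- h$transitions[k, ]
    } else {
      tp <- c(MM = 1, MI = 0, MD = 0, IM = 1, II = 0, DM = 1, DD = 0)
    }
    out <- c(out,
      sprintf("  %5d   %s %6d %s - - -", k,
              paste(sprintf("%-8s", hmmer_num(h$match_emissions[k, ])),
                    collapse = " "),
              h$match_map[k], tolower(cons[k])),
      paste0("          ", paste(sprintf("%-8s",
        hmmer_num(h$insert_emissions[k, ])), collapse = " ")),
      paste0("          ", paste(sprintf("%-8s", hmmer_num(tp)),
        collapse = " ")))
  }
  writeLines(c(out, "//"), path)
  invisible(path)
}

#' Best-effort import of a HMMER3 ASCII model
#'
#' Reads match/insert emissions and node transitions from the log-prob
#' lines and renormalises; prior structure, alignment map details and
#' E-value statistics are not reconstructed.
#'
#' @param path HMMER3 ASCII file
#' @return `profile_hmm`
#' @export
read_hmmer3 <- function(path) {
  ln <- sub("\r$", "", readLines(path))
  getf <- function(key) {
    i <- grep(paste0("^", key, "\\s"), ln)
    if (!length(i)) return(NULL)
    trimws(sub(paste0("^", key, "\\s+"), "", ln[i[1]]))
  }
  K <- as.integer(getf("LENG"))
  if (!isTRUE(K >= 1L)) stop("no LENG line; not a HMMER3 file?")
  ga <- getf("GA")
  hmm_i <- grep("^HMM\\s", ln)[1]
  body <- ln[(hmm_i + 2L):length(ln)]
  node_i <- grep("^\\s+\\d+\\s", body)
  p_from <- function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    v[tok == "*"] <- Inf
    exp(-v)
  }
  me <- matrix(0, K, 20L, dimnames = list(NULL, AA20))
  ie <- matrix(0, K, 20L, dimnames = list(NULL, AA20))
  tr7 <- matrix(0, K, 7L)
  mp <- integer(K)
  for (idx in node_i) {
    tok <- strsplit(trimws(body[idx]), "\\s+")[[1]]
    k <- as.integer(tok[1])
    if (is.na(k) || k < 1L || k > K) next
    me[k, ] <- p_from(tok[2:21])
    mp[k] <- suppressWarnings(as.integer(tok[22]))
    ie[k, ] <- p_from(strsplit(trimws(body[idx + 1L]), "\\s+")[[1]][1:20])
    tr7[k, ] <- p_from(strsplit(trimws(body[idx + 2L]), "\\s+")[[1]][1:7])
  }
  # mean-emission backfill for unparsed nodes, then renormalise
  bad <- rowSums(me) <= 0
  if (any(bad)) me[bad, ] <- rep(colMeans(me[!bad, , drop = FALSE]),
                                 each = sum(bad))
  me <- me / rowSums(me)
  bad <- rowSums(ie) <= 0
  if (any(bad)) ie[bad, ] <- rep(aa_background(), each = sum(bad))
  ie <- ie / rowSums(ie)
  tr <- tr7[seq_len(max(K - 1L, 0L)), , drop = FALSE]
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  if (nrow(tr) > 0L) {
    tr[, 1:3] <- tr[, 1:3] / rowSums(tr[, 1:3, drop = FALSE])
    tr[, 4:5] <- tr[, 4:5] / rowSums(tr[, 4:5, drop = FALSE])
    tr[, 6:7] <- tr[, 6:7] / rowSums(tr[, 6:7, drop = FALSE])
  }
  if (any(mp <= 0L) || anyNA(mp)) mp <- seq_len(K)
  h <- structure(list(
    name = if (is.null(getf("NAME"))) basename(path) else getf("NAME"),
    group_label = if (is.null(getf("DESC"))) "" else getf("DESC"),
    n_match = K,
    match_emissions = me,
    insert_emissions = ie,
    transitions = tr,
    background = aa_background(),
    gathering_cutoff = if (is.null(ga)) NULL else
      as.numeric(strsplit(trimws(ga), "\\s+")[[1]][1]),
    source_size = NA_integer_,
    consensus = paste(AA20[max.col(me, ties.method = "first")],
                      collapse = ""),
    match_map = mp,
    score_basis = "full_sequence_forward_bits"
  ), class = "profile_hmm")
  validate_profile_hmm(h)
  h
}
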