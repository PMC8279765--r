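# Profile-HMM estimation from a multiple alignment.
#
# Architecture: match states M_1..M_K, interior insert states I_1..I_{K-1},
# delete states D_2..D_{K-1} reachable between matches; local alignment
# enters at any match state and exits from any match state with uniform
# probability 1/K (flanking residues score 0 in log-odds). Seven transition
# moves per node: MM, MI, MD, IM, II, DM, DD.

#' Model-build settings
#'
#' @param gap_threshold a column becomes a match column when its gap
#'   fraction is strictly below this value (default 0.5)
#' @param pc_scheme emission pseudocount scheme: `"background"` adds
#'   `alpha * 20 * background[r]` to the count of residue `r` (with a
#'   uniform background this is classic Laplace +alpha), `"laplace"` adds
#'   `alpha` per residue regardless of background
#' @param pc_alpha emission pseudocount weight (default 1)
#' @param pc_trans transition pseudocount added to every legal move
#' @param weighting use Henikoff position-based sequence weights
#' @param background residue background frequencies, see [aa_background()]
#' @param insert_emissions `"estimate"` (counts + pseudocounts) or
#'   `"background"` (inserts score 0 in log-odds)
#' @return list of settings for [build_profile()]
#' @export
hmm_config <- function(gap_threshold = 0.5,
                       pc_scheme = c("background", "laplace"),
                       pc_alpha = 1.0,
                       pc_trans = 1.0,
                       weighting = TRUE,
                       background = aa_background(),
                       insert_emissions = c("estimate", "background")) {
  stopifnot(gap_threshold > 0, gap_threshold <= 1,
            pc_alpha > 0, pc_trans > 0,
            length(background) == 20L, all(background > 0))
  list(gap_threshold = gap_threshold,
       pc_scheme = match.arg(pc_scheme),
       pc_alpha = pc_alpha,
       pc_trans = pc_trans,
       weighting = isTRUE(weighting),
       background = setNames(background / sum(background), AA20),
       insert_emissions = match.arg(insert_emissions))
}

# Henikoff position-based weights, normalised to sum to nrow
henikoff_weights <- function(chm) {
  n <- nrow(chm)
  w <- numeric(n)
  for (col in seq_len(ncol(chm))) {
    res <- chm[, col]
    keep <- res != "-" & res != "X"
    if (!any(keep)) next
    tab <- table(res[keep])
    w[keep] <- w[keep] + 1 / (length(tab) * as.numeric(tab[res[keep]]))
  }
  if (sum(w) == 0) rep(1, n) else w * n / sum(w)
}

emission_pseudocounts <- function(config) {
  if (config$pc_scheme == "background")
    config$pc_alpha * 20 * config$background
  else
    setNames(rep(config$pc_alpha, 20L), AA20)
}

#' Build a profile HMM from a multiple alignment
#'
#' Match columns are alignment columns whose gap fraction is below the
#' configured threshold; emissions are (weighted counts + pseudocounts)
#' normalised; transitions are counted from each row's state path with
#' Laplace pseudocounts over the seven legal moves. Insert runs flanked by
#' a delete contribute residues to insert emissions but the node-to-node
#' transition is counted as the direct move (Plan7 has no I-D / D-I moves).
#'
#' @param m a [msa()]
#' @param config see [hmm_config()]
#' @param name model identifier
#' @param group_label structural-group tag (e.g. "Cry", "Cry_Cterm")
#' @return object of class `profile_hmm`
#' @export
build_profile <- function(m, config = hmm_config(), name = "model",
                          group_label = "") {
  stopifnot(inherits(m, "pestiscan_msa"))
  chm <- msa_matrix(m)
  n <- nrow(chm)
  gapfrac <- colMeans(chm == "-")
  is_match <- gapfrac < config$gap_threshold
  K <- sum(is_match)
  if (K == 0L)
    stop("no consensus columns: every alignment column is above the ",
         "gap-fraction threshold ", config$gap_threshold)
  match_cols <- which(is_match)
  node_of <- cumsum(is_match)          # insert columns belong to node 0..K
  w <- if (config$weighting) henikoff_weights(chm) else rep(1, n)
  bg <- config$background
  pc <- emission_pseudocounts(config)

  count_col <- function(cols) {
    cnt <- setNames(numeric(20L), AA20)
    for (cl in cols) {
      res <- chm[, cl]
      keep <- res %in% AA20
      if (any(keep)) {
        tt <- tapply(w[keep], res[keep], sum)
        cnt[names(tt)] <- cnt[names(tt)] + tt
      }
    }
    cnt
  }

  me <- matrix(0, K, 20L, dimnames = list(NULL, AA20))
  for (k in seq_len(K)) {
    cnt <- count_col(match_cols[k]) + pc
    me[k, ] <- cnt / sum(cnt)
  }

  ie <- matrix(rep(bg, each = K), K, 20L, dimnames = list(NULL, AA20))
  if (K > 1L && config$insert_emissions == "estimate") {
    ins_cols <- which(!is_match)
    for (k in seq_len(K - 1L)) {
      cols <- ins_cols[node_of[ins_cols] == k]
      cnt <- count_col(cols) + pc
      ie[k, ] <- cnt / sum(cnt)
    }
  }

  tr <- matrix(config$pc_trans, max(K - 1L, 0L), 7L,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                       "DM", "DD")))
  if (K > 1L) {
    ins_cols <- which(!is_match)
    for (r in seq_len(n)) {
      st <- ifelse(chm[r, match_cols] == "-", "D", "M")
      row_ins <- integer(K)      # residues in insert segment after node k
      if (length(ins_cols) > 0L) {
        resid <- ins_cols[chm[r, ins_cols] != "-"]
        if (length(resid) > 0L) {
          tb <- table(node_of[resid])
          keepk <- as.integer(names(tb))
          ok <- keepk >= 1L & keepk <= K - 1L
          row_ins[keepk[ok]] <- as.integer(tb)[ok]
        }
      }
      for (k in seq_len(K - 1L)) {
        ni <- row_ins[k]
        if (ni > 0L && st[k] == "M" && st[k + 1L] == "M") {
          tr[k, "MI"] <- tr[k, "MI"] + w[r]
          tr[k, "II"] <- tr[k, "II"] + w[r] * (ni - 1L)
          tr[k, "IM"] <- tr[k, "IM"] + w[r]
        } else {
          mv <- paste0(st[k], st[k + 1L])
          tr[k, mv] <- tr[k, mv] + w[r]
        }
      }
    }
    tr[, c("MM", "MI", "MD")] <- tr[, c("MM", "MI", "MD")] /
      rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE])
    tr[, c("IM", "II")] <- tr[, c("IM", "II")] /
      rowSums(tr[, c("IM", "II"), drop = FALSE])
    tr[, c("DM", "DD")] <- tr[, c("DM", "DD")] /
      rowSums(tr[, c("DM", "DD"), drop = FALSE])
  }

  h <- structure(list(
    name = name,
    group_label = group_label,
    n_match = K,
    match_emissions = me,
    insert_emissions = ie,
    transitions = tr,
    background = bg,
    gathering_cutoff = NULL,
    source_size = n,
    # consensus by log-odds (emission over background): robust to
    # background-weighted pseudocounts dominating small families
    consensus = paste(AA20[max.col(sweep(me, 2L, bg, "/"),
                                   ties.method = "first")],
                      collapse = ""),
    match_map = match_cols,
    score_basis = "full_sequence_forward_bits"
  ), class = "profile_hmm")
  validate_profile_hmm(h)
  h
}

#' Validate a profile HMM's internal consistency
#'
#' Checks that every emission and transition distribution sums to 1 within
#' 1e-9, `n_match >= 1`, and the gathering cutoff (when set) is finite.
#'
#' @param h `profile_hmm`
#' @return `h`, invisibly; errors on violation
#' @export
validate_profile_hmm <- function(h) {
  stopifnot(inherits(h, "profile_hmm"))
  if (h$n_match < 1L) stop("model must have at least one match state")
  tol <- 1e-9
  if (any(abs(rowSums(h$match_emissions) - 1) > tol))
    stop("match emission distribution does not sum to 1")
  if (any(abs(rowSums(h$insert_emissions) - 1) > tol))
    stop("insert emission distribution does not sum to 1")
  if (nrow(h$transitions) > 0L) {
    s <- cbind(rowSums(h$transitions[, c("MM", "MI", "MD"), drop = FALSE]),
               rowSums(h$transitions[, c("IM", "II"), drop = FALSE]),
               rowSums(h$transitions[, c("DM", "DD"), drop = FALSE]))
    if (any(abs(s - 1) > tol))
      stop("transition distribution does not sum to 1")
  }
  if (!is.null(h$gathering_cutoff) && !is.finite(h$gathering_cutoff))
    stop("gathering cutoff must be finite")
  invisible(h)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM '%s' [%s]: %d match states, built from %d sequences\n",
              x$name, x$group_label, x$n_match, x$source_size))
  cat(sprintf("  gathering cutoff: %s\n",
              if (is.null(x$gathering_cutoff)) "not set"
              else sprintf("%.1f bits", x$gathering_cutoff)))
  invisible(x)
}
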