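# Gathering-cutoff calibration from bit-score distributions, and the
# four-criterion model validation report.

#' Propose a gathering cutoff from score distributions
#'
#' Fits a Gaussian kernel density (Silverman bandwidth by default) to the
#' pooled scores and places the cutoff at the deepest density minimum
#' between the highest-scoring mode containing the positives and the rest
#' of the distribution. With no background scores, or a unimodal pooled
#' density, the degenerate rule applies: `min(positives) - eps`.
#'
#' @param positive_scores bit scores of labelled true members (>= 1)
#' @param background_scores bit scores of database/negative sequences
#' @param bw kernel bandwidth; `NULL` = Silverman's rule (`bw.nrd0`)
#' @param eps degenerate-rule margin in bits (default 0.5)
#' @param n_grid density grid size
#' @return list: `cutoff`, `density_curve` (data.frame score/density, NULL
#'   in the degenerate no-background case), `degenerate`
#' @export
propose_cutoff <- function(positive_scores, background_scores = numeric(0),
                           bw = NULL, eps = 0.5, n_grid = 512L) {
  stopifnot(length(positive_scores) >= 1L)
  pos <- as.numeric(positive_scores)
  bg <- as.numeric(background_scores)
  if (length(bg) == 0L)
    return(list(cutoff = min(pos) - eps, density_curve = NULL,
                degenerate = TRUE))
  pooled <- c(pos, bg)
  d <- if (is.null(bw)) density(pooled, n = n_grid)
       else density(pooled, bw = bw, n = n_grid)
  curve <- data.frame(score = d$x, density = d$y)
  y <- d$y
  if (max(bg) < min(pos)) {
    # separable: the deepest density point inside the empty gap
    sel <- d$x > max(bg) & d$x < min(pos)
    cutoff <- if (any(sel)) d$x[sel][which.min(y[sel])]
              else (max(bg) + min(pos)) / 2
    return(list(cutoff = cutoff, density_curve = curve,
                degenerate = FALSE))
  }
  interior <- 2:(length(y) - 1L)
  is_max <- c(FALSE, y[interior] >= y[interior - 1L] &
                     y[interior] > y[interior + 1L], FALSE)
  is_min <- c(FALSE, y[interior] <= y[interior - 1L] &
                     y[interior] < y[interior + 1L], FALSE)
  modes <- d$x[is_max]
  if (length(modes) < 2L)
    return(list(cutoff = min(pos) - eps, density_curve = curve,
                degenerate = TRUE))
  # the mode nearest the bulk of the positives
  pos_mode <- modes[which.min(abs(modes - stats::median(pos)))]
  lower_modes <- modes[modes < pos_mode]
  if (length(lower_modes) == 0L)
    return(list(cutoff = min(pos) - eps, density_curve = curve,
                degenerate = TRUE))
  lo <- max(lower_modes)
  in_valley <- d$x > lo & d$x < pos_mode
  if (!any(in_valley))
    return(list(cutoff = min(pos) - eps, density_curve = curve,
                degenerate = TRUE))
  # deepest point of the valley = global argmin between the two modes
  vx <- d$x[in_valley]; vy <- y[in_valley]
  list(cutoff = vx[which.min(vy)], density_curve = curve,
       degenerate = FALSE)
}

score_set <- function(model, seqs) {
  r <- as_seq_records(seqs)
  vapply(seq_len(nrow(r)), function(i)
    score_sequence(model, r$sequence[i], r$id[i])$forward_bits, 0)
}

calibration_report <- function(model_name, pos, bg, cutoff, curve,
                               extra = character(0)) {
  crit <- c(
    positives_above = all(pos >= cutoff),
    extra_matches_reviewable = TRUE,     # informational list attached
    negatives_below = length(bg) == 0L || all(bg < cutoff),
    separation = length(bg) == 0L || (min(pos) - max(bg)) > 0)
  structure(list(model_name = model_name,
                 positive_scores = pos,
                 background_scores = bg,
                 proposed_cutoff = cutoff,
                 criteria_passed = crit,
                 extra_matches = extra,
                 density_curve = curve),
            class = "calibration_report")
}

#' Calibrate a model's gathering cutoff
#'
#' Scores positives and background with the forward algorithm (the score
#' the cutoff gates), proposes a cutoff via [propose_cutoff()] and
#' evaluates the four model-quality criteria. Inseparable score sets are
#' flagged (criterion 4 fails), never an exception.
#'
#' @param model `profile_hmm`
#' @param positives labelled true members ([as_seq_records()])
#' @param background database / negative sequences (may be empty)
#' @param bw,eps passed to [propose_cutoff()]
#' @return `calibration_report`; the input model with the cutoff applied
#'   is in attribute `model`
#' @export
calibrate_cutoff <- function(model, positives, background = NULL,
                             bw = NULL, eps = 0.5) {
  pos <- score_set(model, positives)
  bg <- if (is.null(background)) numeric(0) else score_set(model, background)
  pr <- propose_cutoff(pos, bg, bw = bw, eps = eps)
  rep <- calibration_report(model$name, pos, bg, pr$cutoff,
                            pr$density_curve)
  model$gathering_cutoff <- pr$cutoff
  attr(rep, "model") <- model
  rep
}

#' Validate a model against labelled sets with its existing cutoff
#'
#' The four criteria: (1) every true positive scores at or above the
#' cutoff; (2) additional high-scoring database matches are listed for
#' manual review (informational, always passes); (3) true-negative
#' control sequences are absent or below the cutoff; (4) positive
#' separation between the lowest positive and the highest other score.
#'
#' @param model `profile_hmm` with `gathering_cutoff` set
#' @param positives,negatives labelled sequence sets
#' @param database optional extra sequences scanned for criterion 2's list
#' @return `calibration_report`
#' @export
validate_model <- function(model, positives, negatives, database = NULL) {
  if (is.null(model$gathering_cutoff))
    stop("model '", model$name, "' has no gathering cutoff; run ",
         "calibrate_cutoff() first")
  cutoff <- model$gathering_cutoff
  pos <- score_set(model, positives)
  neg <- if (is.null(negatives)) numeric(0) else score_set(model, negatives)
  extra <- character(0)
  if (!is.null(database)) {
    db <- as_seq_records(database)
    dbs <- score_set(model, db)
    extra <- db$id[dbs >= cutoff]
  }
  calibration_report(model$name, pos, neg, cutoff, NULL, extra = extra)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration report for '%s'\n", x$model_name))
  cat(sprintf("  proposed cutoff: %.2f bits\n", x$proposed_cutoff))
  cat(sprintf("  positives: %d (min %.1f), background: %d%s\n",
              length(x$positive_scores), min(x$positive_scores),
              length(x$background_scores),
              if (length(x$background_scores))
                sprintf(" (max %.1f)", max(x$background_scores)) else ""))
  lab <- c("all positives >= cutoff", "extra matches listed for review",
           "negatives absent/below cutoff", "separation > 0")
  for (i in 1:4)
    cat(sprintf("  [%s] %s\n", if (x$criteria_passed[i]) "pass" else "FAIL",
                lab[i]))
  invisible(x)
}

#' Write a calibration report and its density curve as TSV
#'
#' @param report `calibration_report`
#' @param dir output directory
#' @return paths written, invisibly
#' @export
write_calibration <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(report$model_name, "_calibration.tsv"))
  df <- data.frame(
    model = report$model_name,
    proposed_cutoff = report$proposed_cutoff,
    n_positive = length(report$positive_scores),
    n_background = length(report$background_scores),
    crit1_positives_above = report$criteria_passed[[1]],
    crit2_extra_reviewable = report$criteria_passed[[2]],
    crit3_negatives_below = report$criteria_passed[[3]],
    crit4_separation = report$criteria_passed[[4]])
  write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- p1
  if (!is.null(report$density_curve)) {
    p2 <- file.path(dir, paste0(report$model_name, "_density.tsv"))
    write.table(report$density_curve, p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
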