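# Family-model construction from a clustering of representative sequences.

#' Build profile HMMs for clustered families
#'
#' Every cluster with at least `min_size` members is aligned (built-in
#' progressive aligner by default) and passed to [build_profile()].
#' Clusters below `min_size` produce no multi-sequence model; designated
#' singletons can still be modelled via `single_ids` (mirroring
#' single-sequence models for rare groups).
#'
#' @param clusters a [cluster_set()]
#' @param seqs sequence records covering every clustered id
#' @param min_size minimum members for a family model (default 5)
#' @param config [hmm_config()] passed to [build_profile()]
#' @param aligner function(records) -> [msa()]; default
#'   [align_progressive()]. Supply your own to substitute an external
#'   aligner.
#' @param single_ids ids of singletons that should get a one-sequence model
#' @param group_labels optional named character: id of any cluster member ->
#'   group label stamped on the model
#' @param name_prefix model name prefix (models are `<prefix>_001`, ...)
#' @return named list of `profile_hmm`; per-cluster alignment failures are
#'   collected in attribute `errors` and do not stop the pipeline
#' @export
build_models <- function(clusters, seqs, min_size = 5L,
                         config = hmm_config(),
                         aligner = align_progressive,
                         single_ids = character(0),
                         group_labels = NULL,
                         name_prefix = "fam") {
  stopifnot(inherits(clusters, "cluster_set"), min_size >= 1L)
  r <- as_seq_records(seqs)
  missing <- setdiff(unlist(clusters$clusters), r$id)
  if (length(missing))
    stop("clustered ids missing from the sequence set: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  models <- list()
  errors <- character(0)
  sel <- clusters$clusters[lengths(clusters$clusters) >= min_size]
  singles <- lapply(intersect(single_ids, unlist(clusters$clusters)), identity)
  todo <- c(sel, lapply(unlist(singles), function(id) id))
  todo <- todo[!duplicated(vapply(todo, paste, "", collapse = "\r"))]
  ct <- 0L
  for (cl in todo) {
    ct <- ct + 1L
    nm <- sprintf("%s_%03d", name_prefix, ct)
    lab <- ""
    if (!is.null(group_labels)) {
      hitlab <- group_labels[intersect(cl, names(group_labels))]
      if (length(hitlab)) lab <- hitlab[[1]]
    }
    rows <- r[match(cl, r$id), , drop = FALSE]
    m <- tryCatch({
      aln <- aligner(rows)
      build_profile(aln, config, name = nm, group_label = lab)
    }, error = function(e) e)
    if (inherits(m, "error")) {
      errors <- c(errors, sprintf("%s (%s): %s", nm,
                                  paste(cl, collapse = ","),
                                  conditionMessage(m)))
    } else {
      models[[nm]] <- m
    }
  }
  if (length(errors))
    warning("model building failed for ", length(errors), " cluster(s)")
  attr(models, "errors") <- errors
  models
}

#' Build the C-terminal model for long crystal (Cry) toxins
#'
#' Long Cry proteins carry a C-terminal crystallisation extension beyond
#' the three-domain toxin core. This builds a model from only the
#' post-boundary portion of each sequence; inputs at or below the length
#' threshold are rejected.
#'
#' @param long_sequences sequence records, each longer than `threshold`
#' @param core_boundary integer vector (recycled) of per-sequence split
#'   positions: residues after this 1-based position form the C-terminal
#'   part
#' @param threshold minimal full-sequence length (default 1000 aa;
#'   sequences must be strictly longer)
#' @param config,aligner as in [build_models()]
#' @param name model name
#' @return `profile_hmm` with `group_label = "Cry_Cterm"`
#' @export
make_cterm_model <- function(long_sequences, core_boundary,
                             threshold = 1000L,
                             config = hmm_config(),
                             aligner = align_progressive,
                             name = "cry_cterm") {
  r <- as_seq_records(long_sequences)
  len <- nchar(r$sequence)
  short <- len <= threshold
  if (any(short))
    stop("sequence(s) ", paste(r$id[short], collapse = ", "),
         " are not longer than the long-Cry threshold of ", threshold,
         " aa")
  b <- rep_len(as.integer(core_boundary), nrow(r))
  if (any(b < 1L | b >= len))
    stop("core boundary out of range for ",
         paste(r$id[b < 1L | b >= len], collapse = ", "))
  cterm <- data.frame(id = r$id,
                      sequence = substring(r$sequence, b + 1L),
                      stringsAsFactors = FALSE)
  aln <- aligner(cterm)
  build_profile(aln, config, name = name, group_label = "Cry_Cterm")
}
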