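# Dedup -> similarity graph -> MCL -> family models -> calibration.

test_that("deduplicate merges exact duplicates and substrings only", {
  # exact duplicates merge
  d1 <- deduplicate(c(A = "MKV", B = "MKV"))
  expect_equal(nrow(d1$representatives), 1L)
  # a full-length 100%-identity substring merges; the longest wins
  d2 <- deduplicate(c(A = "MKVLT", B = "KVL"))
  expect_equal(d2$representatives$id, "A")
  expect_equal(d2$clusters$clusters, list(c("A", "B")))
  # one mismatch: no merge
  d3 <- deduplicate(c(A = "MKVLT", B = "MKALT"))
  expect_equal(nrow(d3$representatives), 2L)
  # tie on length: lexicographically smaller id represents
  d4 <- deduplicate(c(Z = "MKV", A = "MKV"))
  expect_equal(d4$representatives$id, "A")
})

test_that("deduplicate is idempotent on its own representatives", {
  set.seed(5)
  seqs <- setNames(
    vapply(1:12, function(i)
      paste(sample(AA20, sample(20:40, 1), TRUE), collapse = ""), ""),
    paste0("s", 1:12))
  seqs["s13"] <- seqs["s1"]                     # duplicate
  seqs["s14"] <- substr(seqs["s2"], 3, 20)      # substring
  d <- deduplicate(seqs)
  d2 <- deduplicate(d$representatives)
  expect_identical(d2$representatives$id, d$representatives$id)
  expect_identical(d2$representatives$sequence, d$representatives$sequence)
})

test_that("similarity graph: symmetry, self-score, and the SW oracle", {
  g <- similarity_graph(tiny_records(a = "MKVAWLTEHH", b = "MKVAWLTEHH",
                                     c = "WWWPPPGGGC"), floor = 10)
  e <- g$edges
  # identical pair's edge weight equals either self-alignment score
  ab <- e$weight[(e$from == "a" & e$to == "b")]
  expect_equal(ab, sw_score("MKVAWLTEHH", "MKVAWLTEHH"))
  expect_equal(ab, naive_sw("MKVAWLTEHH", "MKVAWLTEHH"))
  # the classic textbook pair against the independent implementation
  expect_equal(sw_score("HEAGAWGHEE", "PAWHEAE"),
               naive_sw("HEAGAWGHEE", "PAWHEAE"))
  # random pairs against the naive quadratic implementation
  set.seed(31)
  for (i in 1:8) {
    a <- paste(sample(AA20, sample(5:30, 1), TRUE), collapse = "")
    b <- paste(sample(AA20, sample(5:30, 1), TRUE), collapse = "")
    expect_equal(sw_score(a, b), naive_sw(a, b))
  }
})

barbell_graph <- function() {
  nodes <- c(paste0("a", 1:4), paste0("b", 1:4))
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  for (s in list(paste0("a", 1:4), paste0("b", 1:4)))
    for (i in 1:3) for (j in (i + 1):4)
      edges <- rbind(edges, data.frame(from = s[i], to = s[j], weight = 10))
  edges <- rbind(edges, data.frame(from = "a4", to = "b1", weight = 1))
  structure(list(nodes = nodes, edges = edges),
            class = "similarity_graph")
}

test_that("MCL: components, barbell, stochasticity, order invariance", {
  # two disconnected 3-cliques -> exactly their components
  nodes <- c(paste0("x", 1:3), paste0("y", 1:3))
  edges <- rbind(
    expand.grid(from = paste0("x", 1:2), to = "x3",
                stringsAsFactors = FALSE),
    data.frame(from = "x1", to = "x2"),
    expand.grid(from = paste0("y", 1:2), to = "y3",
                stringsAsFactors = FALSE),
    data.frame(from = "y1", to = "y2"))
  edges$weight <- 5
  g <- structure(list(nodes = nodes, edges = edges),
                 class = "similarity_graph")
  cl <- mcl_cluster(g)
  expect_equal(canon_partition(cl$clusters),
               list(c("x1", "x2", "x3"), c("y1", "y2", "y3")))
  expect_equal(canon_partition(cl$clusters),
               canon_partition(oracle_mcl(nodes, edges)))

  # single node
  g1 <- structure(list(nodes = "solo",
                       edges = edges[0, ]), class = "similarity_graph")
  expect_equal(mcl_cluster(g1)$clusters, list("solo"))

  # barbell: weak bridge split at inflation 2, confirmed by the
  # independent implementation
  gb <- barbell_graph()
  clb <- mcl_cluster(gb, inflation = 2.0)
  expect_equal(canon_partition(clb$clusters),
               list(paste0("a", 1:4), paste0("b", 1:4)))
  expect_equal(canon_partition(clb$clusters),
               canon_partition(oracle_mcl(gb$nodes, gb$edges)))

  # column-stochastic through every iteration
  expect_lt(attr(clb, "stochastic_dev"), 1e-9)

  # partition property + input-order invariance
  perm <- gb
  set.seed(2)
  perm$nodes <- sample(perm$nodes)
  o <- sample(nrow(perm$edges))
  perm$edges <- perm$edges[o, ]
  clp <- mcl_cluster(perm, inflation = 2.0)
  expect_equal(canon_partition(clp$clusters), canon_partition(clb$clusters))
  expect_equal(sort(unlist(clb$clusters)), sort(gb$nodes))
})

test_that("MCL matches the independent implementation on random graphs", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 9L
    nodes <- paste0("n", 1:n)
    # two planted groups with dense in-group, sparse cross edges
    grp <- rep(1:2, length.out = n)
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (grp[i] == grp[j]) 0.9 else 0.08
      if (runif(1) < p)
        edges <- rbind(edges, data.frame(
          from = nodes[i], to = nodes[j],
          weight = if (grp[i] == grp[j]) runif(1, 8, 12)
                   else runif(1, 0.5, 1.5)))
    }
    g <- structure(list(nodes = nodes, edges = edges),
                   class = "similarity_graph")
    expect_equal(canon_partition(mcl_cluster(g)$clusters),
                 canon_partition(oracle_mcl(nodes, edges)))
  }
})

test_that("build_models honours min_size and the subset property", {
  fx <- generate_family_fixture(fixture_spec(seed = 13, n_families = 3,
                                             family_size = 6,
                                             family_length = 80,
                                             n_decoys = 0))
  rec <- fx$records
  fams <- split(rec$id, fx$labels$family)
  # clusters of sizes 4, 5, 6
  cl <- cluster_set(list(fams[[1]][1:4], fams[[2]][1:5], fams[[3]][1:6]))
  m5 <- build_models(cl, rec, min_size = 5L)
  expect_length(m5, 2L)
  m1 <- build_models(cl, rec, min_size = 1L)
  expect_length(m1, 3L)
  m6 <- build_models(cl, rec, min_size = 6L)
  expect_length(m6, 1L)
  # larger min_size yields a subset (by member sets) of the smaller run
  members <- function(ms) lapply(ms, function(h) h$source_size)
  expect_true(all(unlist(members(m6)) %in% unlist(members(m5))))
  # designated singleton -> 1-sequence model whose consensus is the seq
  cls <- cluster_set(list(fams[[1]][1], fams[[2]][1:5]))
  ms <- build_models(cls, rec, min_size = 5L, single_ids = fams[[1]][1])
  expect_length(ms, 2L)
  single <- Filter(function(h) h$source_size == 1L, ms)[[1]]
  expect_identical(single$consensus,
                   rec$sequence[rec$id == fams[[1]][1]])
})

test_that("group labels propagate to models", {
  fx <- generate_family_fixture(fixture_spec(seed = 14, n_families = 1,
                                             family_size = 5,
                                             family_length = 60,
                                             n_decoys = 0))
  cl <- cluster_set(list(fx$records$id))
  labs <- setNames(rep("Vip", nrow(fx$records)), fx$records$id)
  m <- build_models(cl, fx$records, min_size = 5L, group_labels = labs)
  expect_identical(m[[1]]$group_label, "Vip")
})

test_that("C-terminal model: threshold gate and signal direction", {
  set.seed(77)
  # shared conserved 400-aa C-terminus, divergent 800-aa cores
  cterm_anc <- paste(sample(AA20, 400, TRUE), collapse = "")
  mut <- function(s, d) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < d
    ch[hit] <- sample(AA20, sum(hit), TRUE)
    paste(ch, collapse = "")
  }
  longs <- tiny_records(
    c1 = paste0(paste(sample(AA20, 800, TRUE), collapse = ""),
                mut(cterm_anc, 0.1)),
    c2 = paste0(paste(sample(AA20, 800, TRUE), collapse = ""),
                mut(cterm_anc, 0.1)),
    c3 = paste0(paste(sample(AA20, 800, TRUE), collapse = ""),
                mut(cterm_anc, 0.1)))

  # length gate: 999 rejected, 1001 accepted
  expect_error(make_cterm_model(
    tiny_records(s = paste(rep("A", 999), collapse = "")), 700),
    "1000")
  ok <- make_cterm_model(
    tiny_records(s = paste(sample(AA20, 1001, TRUE), collapse = "")), 700)
  expect_identical(ok$group_label, "Cry_Cterm")
  expect_lte(ok$n_match, 301L)

  cterm_model <- make_cterm_model(longs, core_boundary = 800)
  core_model <- build_profile(
    align_progressive(tiny_records(c1 = substr(longs$sequence[1], 1, 800),
                                   c2 = substr(longs$sequence[2], 1, 800),
                                   c3 = substr(longs$sequence[3], 1, 800))),
    name = "core_control")
  heldout <- mut(cterm_anc, 0.1)
  expect_gt(score_sequence(cterm_model, heldout)$forward_bits,
            score_sequence(core_model, heldout)$forward_bits)
})

test_that("cutoff proposal: degenerate rule, separability, bimodal KDE", {
  # positives only -> min - eps
  expect_equal(propose_cutoff(c(100, 110, 120))$cutoff, 99.5)
  # separable two-group case: all positives >= cutoff, all background <
  pc <- propose_cutoff(c(100, 110), c(10, 12))
  expect_true(all(c(100, 110) >= pc$cutoff))
  expect_true(all(c(10, 12) < pc$cutoff))
  # bimodal mixture: cutoff in the valley, classification error 0
  set.seed(42)
  pos <- rnorm(50, 100, 3)
  bg <- rnorm(200, 30, 3)
  r <- propose_cutoff(pos, bg)
  expect_gt(r$cutoff, 45); expect_lt(r$cutoff, 85)
  expect_true(all(pos >= r$cutoff))
  expect_true(all(bg < r$cutoff))
  # oracle: direct argmin of the same KDE between the two sample means
  d <- density(c(pos, bg), n = 512)
  sel <- d$x > mean(bg) & d$x < mean(pos)
  expect_equal(r$cutoff, d$x[sel][which.min(d$y[sel])], tolerance = 1e-9)
})

test_that("background shift never creates false positives while separable", {
  set.seed(8)
  pos <- rnorm(30, 90, 2)
  bg <- rnorm(60, 20, 2)
  for (shift in c(0, 10, 25, 40)) {
    r <- propose_cutoff(pos, bg + shift)
    if (min(pos) > max(bg + shift))
      expect_equal(sum(bg + shift >= r$cutoff), 0L)
  }
})

test_that("calibrate_cutoff + validate_model on a fixture family", {
  fx <- generate_family_fixture(fixture_spec(seed = 3, n_families = 1,
                                             family_size = 6,
                                             family_length = 120,
                                             n_decoys = 15))
  rec <- fx$records
  pos <- rec[fx$labels$label == "positive", ]
  neg <- rec[fx$labels$label == "negative", ]
  h <- build_profile(align_progressive(pos), name = "famA")
  rep <- calibrate_cutoff(h, pos, neg)
  expect_true(rep$proposed_cutoff > max(rep$background_scores))
  expect_true(rep$proposed_cutoff <= min(rep$positive_scores))
  hcal <- attr(rep, "model")
  expect_identical(hcal$gathering_cutoff, rep$proposed_cutoff)
  v <- validate_model(hcal, pos, neg)
  expect_length(v$criteria_passed, 4L)
  expect_true(all(v$criteria_passed))
  # one positive below cutoff -> criterion 1 fails
  h2 <- hcal
  h2$gathering_cutoff <- max(rep$positive_scores) + 1
  v2 <- validate_model(h2, pos, neg)
  expect_false(v2$criteria_passed[[1]])
  # inseparable inputs flag criterion 4, no exception
  v3 <- validate_model(hcal, neg[1:3, ], pos[1:2, ])
  expect_false(v3$criteria_passed[[4]])
})

test_that("pipeline determinism: same seed -> byte-identical model files", {
  run <- function(dir) {
    fx <- generate_family_fixture(fixture_spec(seed = 9, n_families = 2,
                                               family_size = 5,
                                               family_length = 80,
                                               n_decoys = 0))
    dd <- deduplicate(fx$records)
    g <- similarity_graph(dd$representatives, floor = 50)
    cl <- mcl_cluster(g)
    models <- build_models(cl, dd$representatives, min_size = 5L)
    write_model_collection(models, dir)
    dir
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run(d1); run(d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})
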