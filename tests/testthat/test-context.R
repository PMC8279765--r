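# Flank extraction, re-annotation, identity blocks, SVG rendering.

fake_hit <- function(record, start0, end0, strand = "+") {
  data.frame(query_id = "q", model_name = "m", group_label = "",
             bits = 100, cutoff = 50, above_cutoff = TRUE, rank = 1L,
             span_start = 0L, span_end = 1L, record_id = record,
             strand = strand, start = start0, end = end0,
             stringsAsFactors = FALSE)
}

plain_record <- function(name, seqstr, topology = "linear",
                         features = list()) {
  structure(list(name = name, length = nchar(seqstr),
                 topology = topology, definition = "",
                 sequence = seqstr, features = features),
            class = "genbank_record")
}

test_that("flank arithmetic: interior, clipped, zero-flank", {
  set.seed(1)
  g <- plain_record("r1", pestiscan:::random_dna(20000))
  # centrally placed gene takes 5000 bp each side
  r <- extract_flanks(list(g), fake_hit("r1", 6000L, 7000L))
  expect_equal(r$region_interval, c(1000L, 12000L))
  expect_equal(nchar(r$sequence), 11000L)
  expect_equal(r$anchor_interval, c(5000L, 6000L))
  expect_false(r$truncated_left); expect_false(r$truncated_right)
  # clipped at the left edge
  r2 <- extract_flanks(list(g), fake_hit("r1", 2000L, 3000L))
  expect_equal(r2$region_interval, c(0L, 8000L))
  expect_true(r2$truncated_left); expect_false(r2$truncated_right)
  # flank 0 reduces to the gene
  r3 <- extract_flanks(list(g), fake_hit("r1", 6000L, 7000L), flank = 0L)
  expect_equal(nchar(r3$sequence), 1000L)
  expect_identical(r3$sequence, substr(g$sequence, 6001L, 7000L))
  # protein-only hits are a usage error
  h <- fake_hit("r1", NA_integer_, NA_integer_)
  h$record_id <- NA_character_
  expect_error(extract_flanks(list(g), h), "scan_genome")
})

test_that("flank arithmetic property over random placements", {
  set.seed(23)
  g <- plain_record("r", pestiscan:::random_dna(15000))
  for (i in 1:20) {
    s <- sample(0:13999, 1)
    e <- s + sample(200:1000, 1)
    if (e > 15000) next
    r <- extract_flanks(list(g), fake_hit("r", s, e))
    expect_equal(nchar(r$sequence),
                 (e - s) + min(5000L, s) + min(5000L, 15000L - e))
  }
})

test_that("circular records wrap flanks across the origin", {
  set.seed(3)
  g <- plain_record("c1", pestiscan:::random_dna(12000),
                    topology = "circular")
  # gene near the origin: flanks wrap, nothing truncated
  r <- extract_flanks(list(g), fake_hit("c1", 100L, 700L))
  expect_equal(nchar(r$sequence), 600L + 10000L)
  expect_true(r$wrapped)
  expect_false(r$truncated_left)
  expect_identical(substr(r$sequence, 5001L, 5600L),
                   substr(g$sequence, 101L, 700L))
})

test_that("annotation: no-start sequences, planted ORFs, both strands", {
  # poly-A has no start codon in any frame
  r <- structure(list(region_id = "t", record_id = "t",
                      region_interval = c(0L, 900L),
                      sequence = paste(rep("A", 900), collapse = ""),
                      features = data.frame(start = integer(0),
                                            end = integer(0),
                                            strand = character(0),
                                            kind = character(0),
                                            label = character(0)),
                      anchor_interval = c(0L, 10L),
                      truncated_left = FALSE, truncated_right = FALSE,
                      wrapped = FALSE), class = "context_region")
  expect_equal(nrow(annotate_region(r)$features), 0L)

  # a planted 150-codon ORF is reported exactly
  set.seed(41)
  aa <- paste0("M", paste(sample(AA20, 149, TRUE), collapse = ""))
  orf_dna <- back_translate(aa)          # 453 bp incl stop
  # an in-frame stop right before the planted start pins the ORF there
  lead <- paste0(pestiscan:::random_dna(498), "TAA")
  seqstr <- paste0(lead, orf_dna, pestiscan:::random_dna(500))
  r$sequence <- seqstr
  r$region_interval <- c(0L, nchar(seqstr))
  ann <- annotate_region(r, min_orf_aa = 120L)
  plus <- ann$features[ann$features$strand == "+", ]
  expect_true(any(plus$start == 501L & plus$end == 501L + 453L))

  # reverse-complemented planting mirrors coordinates, strand '-'
  r2 <- r
  r2$sequence <- pestiscan:::revcomp_dna(seqstr)
  ann2 <- annotate_region(r2, min_orf_aa = 120L)
  L <- nchar(seqstr)
  minus <- ann2$features[ann2$features$strand == "-", ]
  expect_true(any(minus$start == L - (501L + 453L) & minus$end == L - 501L))
  # independent check: forward-scan the reverse complement and mirror
  fwd <- find_orfs(seqstr, min_aa = 120L)
  fwd_plus <- fwd[fwd$strand == "+", ]
  mirrored <- data.frame(start = L - fwd_plus$end0, end = L - fwd_plus$start0)
  expect_true(all(paste(mirrored$start, mirrored$end) %in%
                  paste(minus$start, minus$end)))

  # every reported ORF translates without internal stops
  expect_false(any(grepl("\\*", ann$features$label)))
  orfs <- find_orfs(seqstr, min_aa = 50L)
  expect_false(any(grepl("\\*", substr(orfs$aa, 1, nchar(orfs$aa)))))

  expect_error(find_orfs("ACGTRRR"), "non-IUPAC")
})

test_that("ORFs overlapping carried-over CDS are suppressed", {
  set.seed(6)
  aa <- paste0("M", paste(sample(AA20, 99, TRUE), collapse = ""))
  orf_dna <- back_translate(aa)
  seqstr <- paste0(pestiscan:::random_dna(300), orf_dna,
                   pestiscan:::random_dna(300))
  r <- structure(list(region_id = "t2", record_id = "t2",
                      region_interval = c(0L, nchar(seqstr)),
                      sequence = seqstr,
                      features = data.frame(start = 300L,
                                            end = 300L + nchar(orf_dna),
                                            strand = "+", kind = "CDS",
                                            label = "planted",
                                            stringsAsFactors = FALSE),
                      anchor_interval = c(300L, 300L + nchar(orf_dna)),
                      truncated_left = FALSE, truncated_right = FALSE,
                      wrapped = FALSE), class = "context_region")
  ann <- annotate_region(r, min_orf_aa = 80L)
  orfs <- ann$features[ann$features$kind == "ORF", ]
  ov <- pmin(orfs$end, r$features$end[1]) - pmax(orfs$start,
                                                 r$features$start[1])
  expect_true(all(ov / (orfs$end - orfs$start) <= 0.8))
})

region_from_seq <- function(id, seqstr) {
  structure(list(region_id = id, record_id = id,
                 region_interval = c(0L, nchar(seqstr)),
                 sequence = seqstr,
                 features = data.frame(start = integer(0),
                                       end = integer(0),
                                       strand = character(0),
                                       kind = character(0),
                                       label = character(0)),
                 anchor_interval = c(0L, 10L),
                 truncated_left = FALSE, truncated_right = FALSE,
                 wrapped = FALSE), class = "context_region")
}

test_that("identity blocks: self, reverse complement, planted cassette", {
  set.seed(12)
  s <- pestiscan:::random_dna(3000)
  ra <- region_from_seq("A", s)
  # exact copy -> one full-length block at 100%
  bl <- compare_regions(list(ra, region_from_seq("B", s)))
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$a_start, 0L); expect_equal(bl$a_end, 3000L)
  expect_equal(bl$pct_identity, 100)
  expect_identical(bl$orientation, "same")
  # reverse complement -> full-length inverted block
  bli <- compare_regions(list(ra, region_from_seq("C",
                                pestiscan:::revcomp_dna(s))))
  expect_equal(nrow(bli), 1L)
  expect_identical(bli$orientation, "inverted")
  expect_equal(bli$a_end - bli$a_start, 3000L)

  # planted 2000 bp cassette at ~90% identity amid unrelated flanks
  set.seed(13)
  cass <- pestiscan:::random_dna(2000)
  r1 <- region_from_seq("P1", paste0(pestiscan:::random_dna(1500), cass,
                                     pestiscan:::random_dna(1500)))
  cass2 <- pestiscan:::mutate_dna(cass, 0.9)
  r2 <- region_from_seq("P2", paste0(pestiscan:::random_dna(1200), cass2,
                                     pestiscan:::random_dna(1800)))
  bl2 <- compare_regions(list(r1, r2))
  expect_equal(nrow(bl2), 1L)
  ov <- min(bl2$a_end, 3500) - max(bl2$a_start, 1500)
  expect_gte(ov / 2000, 0.95)
  # oracle: direct comparison of the planted copies
  true_ident <- 100 * mean(strsplit(cass, "")[[1]] ==
                           strsplit(cass2, "")[[1]])
  expect_lt(abs(bl2$pct_identity - true_ident), 3)
})

test_that("blocks are reciprocal and null flanks stay silent", {
  set.seed(14)
  cass <- pestiscan:::random_dna(1500)
  r1 <- region_from_seq("X1", paste0(pestiscan:::random_dna(1000), cass,
                                     pestiscan:::random_dna(1000)))
  r2 <- region_from_seq("X2", paste0(pestiscan:::random_dna(800),
                                     pestiscan:::mutate_dna(cass, 0.92),
                                     pestiscan:::random_dna(1200)))
  ab <- compare_regions(list(r1, r2))
  ba <- compare_regions(list(r2, r1))
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab$a_start, ba$b_start)
  expect_equal(ab$b_start, ba$a_start)
  expect_equal(ab$pct_identity, ba$pct_identity, tolerance = 1e-9)

  # unrelated random regions: no blocks (seeded null check)
  for (seed in 1:5) {
    set.seed(1000 + seed)
    n1 <- region_from_seq("N1", pestiscan:::random_dna(4000))
    n2 <- region_from_seq("N2", pestiscan:::random_dna(4000))
    expect_equal(nrow(compare_regions(list(n1, n2))), 0L)
  }
})

test_that("short regions are skipped with a warning", {
  r1 <- region_from_seq("S1", "ACGTACGTA")
  r2 <- region_from_seq("S2", "ACGTACGTA")
  expect_warning(b <- compare_regions(list(r1, r2)), "shorter than k")
  expect_equal(nrow(b), 0L)
})

test_that("SVG rendering is valid and deterministic", {
  set.seed(15)
  s <- pestiscan:::random_dna(2500)
  ra <- region_from_seq("R1", s); rb <- region_from_seq("R2", s)
  bl <- compare_regions(list(ra, rb))
  d <- withr::local_tempdir()
  p1 <- file.path(d, "one.svg")
  render_comparison(list(ra), bl[0, ], p1)
  ln <- readLines(p1)
  expect_true(grepl("^<svg", ln[1]))
  expect_identical(ln[length(ln)], "</svg>")
  expect_true(xml2::xml_name(xml2::read_xml(p1)) == "svg")

  p2 <- file.path(d, "two_a.svg"); p3 <- file.path(d, "two_b.svg")
  render_comparison(list(ra, rb), bl, p2,
                    tsv_path = file.path(d, "blocks.tsv"))
  render_comparison(list(ra, rb), bl, p3)
  expect_identical(readLines(p2), readLines(p3))   # byte-identical
  # identical regions: the full-width trapezoid at the darkest shade
  expect_true(any(grepl("rgb(50,50,50)", readLines(p2), fixed = TRUE)))
  expect_true(file.exists(file.path(d, "blocks.tsv")))
})

test_that("region GenBank round trip", {
  set.seed(16)
  g <- plain_record("rr", pestiscan:::random_dna(8000))
  reg <- annotate_region(extract_flanks(list(g), fake_hit("rr", 3000L,
                                                          3900L)),
                         min_orf_aa = 60L)
  d <- withr::local_tempfile(fileext = ".gbk")
  write_region(reg, d)
  back <- read_genbank(d)
  expect_length(back, 1L)
  expect_identical(back[[1]]$sequence, reg$sequence)
  expect_equal(length(back[[1]]$features) -
                 sum(vapply(back[[1]]$features,
                            function(f) f$kind == "source", TRUE)),
               nrow(reg$features))
})
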