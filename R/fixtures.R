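# Seeded synthetic-data generator: protein families with decoys, and
# GenBank genomes with planted toxin cassettes. Stands in for curated
# database material at desk scale; all randomness flows through the
# spec's seed.

#' Synthetic-fixture specification
#'
#' Defaults describe a desk-scale stand-in for a curated toxin family
#' collection: a few families of realistic size and length, within-family
#' divergence typical of a curated structural subgroup, composition-
#' shuffled decoys, and a plasmid-sized replicon for genomic tests.
#'
#' @param seed integer seed; a fixed seed makes every generated artifact
#'   byte-identical across runs
#' @param n_families number of protein families
#' @param family_size members per family
#' @param family_length ancestor length in residues
#' @param divergence expected substitutions per site within a family,
#'   in `[0, 1)`
#' @param n_decoys composition-shuffled negative sequences
#' @param genome_length replicon size in bp
#' @param gc replicon GC content (default 0.35, AT-rich like a Bt
#'   plasmid)
#' @return list of class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1L, n_families = 3L, family_size = 8L,
                         family_length = 300L, divergence = 0.15,
                         n_decoys = 40L, genome_length = 30000L,
                         gc = 0.35) {
  stopifnot(divergence >= 0, divergence < 1, n_families >= 0,
            family_size >= 0, n_decoys >= 0, genome_length >= 0)
  structure(list(seed = as.integer(seed), n_families = n_families,
                 family_size = family_size,
                 family_length = family_length, divergence = divergence,
                 n_decoys = n_decoys, genome_length = genome_length,
                 gc = gc), class = "fixture_spec")
}

random_protein <- function(n, freqs = aa_background()) {
  paste(sample(AA20, n, replace = TRUE, prob = freqs), collapse = "")
}

# substitute each site with probability `divergence`, to a uniformly
# chosen different residue (so realised identity carries back-mutation)
mutate_protein <- function(seq, divergence) {
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < divergence
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(r)
      sample(setdiff(AA20, r), 1L), "")
  paste(ch, collapse = "")
}

#' Generate a labelled synthetic protein-family fixture
#'
#' Each family is a random ancestor mutated independently per member at
#' the stated divergence (substitutions only); decoys are sequences drawn
#' from the pooled family composition (shuffled composition, no family
#' signal).
#'
#' @param spec a [fixture_spec()]
#' @param dir optional output directory; writes `families.fasta`,
#'   `decoys.fasta` and `labels.tsv`
#' @return list: `records` (sequence data.frame), `labels` (data.frame
#'   id/label/family), `spec`
#' @export
generate_family_fixture <- function(spec = fixture_spec(), dir = NULL) {
  set.seed(spec$seed)
  ids <- character(0); seqs <- character(0)
  labels <- data.frame(id = character(0), label = character(0),
                       family = character(0), stringsAsFactors = FALSE)
  for (f in seq_len(spec$n_families)) {
    anc <- random_protein(spec$family_length)
    fam <- sprintf("fam%02d", f)
    for (m in seq_len(spec$family_size)) {
      id <- sprintf("%s_m%02d", fam, m)
      ids <- c(ids, id)
      seqs <- c(seqs, mutate_protein(anc, spec$divergence))
      labels <- rbind(labels, data.frame(id = id, label = "positive",
                                         family = fam))
    }
  }
  pool <- if (length(seqs)) table(factor(unlist(strsplit(seqs, "")),
                                         levels = AA20))
          else setNames(rep(1, 20), AA20)
  pool <- as.numeric(pool) + 1
  for (d in seq_len(spec$n_decoys)) {
    id <- sprintf("decoy_%03d", d)
    ids <- c(ids, id)
    seqs <- c(seqs, random_protein(spec$family_length, pool))
    labels <- rbind(labels, data.frame(id = id, label = "negative",
                                       family = ""))
  }
  rec <- data.frame(id = ids, sequence = seqs, source_tag = "synthetic",
                    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(rec[labels$label == "positive", ],
                file.path(dir, "families.fasta"))
    if (any(labels$label == "negative"))
      write_fasta(rec[labels$label == "negative", ],
                  file.path(dir, "decoys.fasta"))
    write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(records = rec, labels = labels, spec = spec)
}

CODON_TABLE11 <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc <- Biostrings::getGeneticCode("11")
      code <<- split(names(gc), unname(gc))
    }
    code
  }
})

#' Back-translate a protein with uniform synonymous codon choice
#'
#' @param aa protein string (no ambiguity codes)
#' @param stop append a TAA stop codon
#' @return DNA string (seeded externally via `set.seed`)
#' @export
back_translate <- function(aa, stop = TRUE) {
  tab <- CODON_TABLE11()
  ch <- strsplit(toupper(aa), "")[[1]]
  cod <- vapply(ch, function(r) {
    opts <- tab[[r]]
    if (is.null(opts)) stop("cannot back-translate residue '", r, "'")
    opts[sample.int(length(opts), 1L)]
  }, "")
  # make the first codon a canonical start
  if (length(cod) && ch[1] == "M") cod[1] <- "ATG"
  paste0(paste(cod, collapse = ""), if (stop) "TAA" else "")
}

random_dna <- function(n, gc = 0.35) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substitution-only DNA mutation to a target identity
mutate_dna <- function(s, identity) {
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) >= identity
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(ch, collapse = "")
}

make_record <- function(name, seqstr, feats, topology = "linear") {
  structure(list(name = name, length = nchar(seqstr),
                 topology = topology,
                 definition = "synthetic replicon", sequence = seqstr,
                 features = feats), class = "genbank_record")
}

cds_feature <- function(start1, end1, strand, locus_tag, translation) {
  list(kind = "CDS", start = start1, end = end1, strand = strand,
       parts = cbind(start = start1, end = end1),
       qualifiers = list(locus_tag = locus_tag,
                         translation = translation))
}

#' Generate a synthetic GenBank genome fixture with a planted cassette
#'
#' Builds a random-composition replicon carrying a back-translated toxin
#' gene, optional conserved flank genes (the cassette), and optionally a
#' second replicon sharing the cassette at a stated nucleotide identity
#' amid an unrelated backbone. Truth intervals are returned (and written
#' as TSV).
#'
#' @param protein the toxin protein to plant (string); start residue
#'   should be M
#' @param seed integer seed
#' @param genome_length replicon length (must fit cassette + 2 x 5000 bp)
#' @param flank_genes number of conserved flank genes on each side
#' @param flank_gene_aa length of each flank gene in residues
#' @param second_identity if non-NULL, also emit a second replicon whose
#'   cassette copy has this nucleotide identity (0-1]
#' @param annotate write CDS features (set FALSE for the unannotated
#'   ORF-calling route)
#' @param gc backbone GC content
#' @param dir optional output directory (`genome.gbk`, `truth.tsv`)
#' @return list: `records` (list of `genbank_record`), `truth`
#'   (data.frame record/label/start0/end0/strand)
#' @export
generate_genome_fixture <- function(protein, seed = 1L,
                                    genome_length = 30000L,
                                    flank_genes = 2L,
                                    flank_gene_aa = 120L,
                                    second_identity = NULL,
                                    annotate = TRUE, gc = 0.35,
                                    dir = NULL) {
  set.seed(seed)
  protein <- clean_protein(protein)
  if (!startsWith(protein, "M")) protein <- paste0("M", protein)
  gene <- back_translate(protein)
  spacer <- function() random_dna(sample(120:280, 1L), gc)
  parts <- character(0)
  anno <- list()   # label, aa, strand for each cassette gene in order
  for (i in seq_len(flank_genes)) {
    aa <- paste0("M", random_protein(flank_gene_aa - 1L))
    anno[[length(anno) + 1L]] <- list(label = sprintf("flankL%02d", i),
                                      aa = aa, is_anchor = FALSE)
  }
  anno[[length(anno) + 1L]] <- list(label = "toxin", aa = protein,
                                    is_anchor = TRUE)
  for (i in seq_len(flank_genes)) {
    aa <- paste0("M", random_protein(flank_gene_aa - 1L))
    anno[[length(anno) + 1L]] <- list(label = sprintf("flankR%02d", i),
                                      aa = aa, is_anchor = FALSE)
  }
  cass_parts <- character(0)
  gene_info <- list()
  for (g in anno) {
    sp <- spacer()
    dna <- if (g$is_anchor) gene else back_translate(g$aa)
    cass_parts <- c(cass_parts, sp, dna)
    gene_info[[length(gene_info) + 1L]] <-
      list(label = g$label, aa = g$aa, len = nchar(dna),
           offset_in_cassette = sum(nchar(cass_parts)) - nchar(dna),
           is_anchor = g$is_anchor)
  }
  cassette <- paste(cass_parts, collapse = "")
  if (genome_length < nchar(cassette) + 2L * 5000L)
    stop("genome_length ", genome_length, " too small: cassette is ",
         nchar(cassette), " bp and needs 5000 bp clearance on each side")
  build_replicon <- function(name, cass) {
    lead_n <- (genome_length - nchar(cass)) %/% 2L
    tail_n <- genome_length - nchar(cass) - lead_n
    seqstr <- paste0(random_dna(lead_n, gc), cass, random_dna(tail_n, gc))
    feats <- list()
    truth <- data.frame(record = character(0), label = character(0),
                        start0 = integer(0), end0 = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    for (gi in gene_info) {
      s0 <- lead_n + gi$offset_in_cassette
      e0 <- s0 + gi$len
      # translate from the replicon itself so a mutated cassette copy
      # carries its real (possibly degraded) product
      aa_here <- translate_cds(substr(seqstr, s0 + 1L, e0))
      if (annotate)
        feats[[length(feats) + 1L]] <- cds_feature(
          s0 + 1L, e0, "+", paste0(name, "_", gi$label), aa_here)
      truth <- rbind(truth, data.frame(
        record = name, label = gi$label, start0 = s0, end0 = e0,
        strand = "+", stringsAsFactors = FALSE))
    }
    list(rec = make_record(name, seqstr, feats), truth = truth)
  }
  r1 <- build_replicon("synplasmid1", cassette)
  records <- list(r1$rec)
  truth <- r1$truth
  if (!is.null(second_identity)) {
    cass2 <- mutate_dna(cassette, second_identity)
    r2 <- build_replicon("synplasmid2", cass2)
    records <- c(records, list(r2$rec))
    truth <- rbind(truth, r2$truth)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genbank(records, file.path(dir, "genome.gbk"))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(records = records, truth = truth)
}
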