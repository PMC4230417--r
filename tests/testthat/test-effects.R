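# One plus-strand two-exon gene with a fully known CDS:
#   codons: ATG TGG AAA CCC GGG TAC TTG TAA -> protein MWKPGYL*
# exon1 carries the 5' UTR and CDS bases 1-12, exon2 CDS bases 13-24 and the
# 3' UTR; the single intron is GT..AG.
make_effect_genome <- function() {
  cds <- "ATGTGGAAACCCGGGTACTTGTAA"
  utr5 <- "TTTTTTTTTT"; utr3 <- "CCCCCCCCCC"
  intron <- paste0("GT", strrep("A", 20), "AG")
  gene_seq <- paste0(utr5, substr(cds, 1, 12), intron, substr(cds, 13, 24),
                     utr3)
  pad <- strrep("ACGT", 25)   # 100 bp
  chrom_seq <- paste0(pad, gene_seq, pad)
  gs <- 101L                              # gene start
  exon1 <- c(gs, gs + 21L)                # utr5 + 12 CDS bases
  intron_iv <- c(gs + 22L, gs + 45L)
  exon2 <- c(gs + 46L, gs + 67L)          # 12 CDS bases + utr3
  cds1 <- c(gs + 10L, gs + 21L)
  cds2 <- c(gs + 46L, gs + 57L)
  feats <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(
      start = c(gs, gs, exon1[1], exon2[1], cds1[1], cds2[1], gs,
                gs + 58L),
      end = c(gs + 67L, gs + 67L, exon1[2], exon2[2], cds1[2], cds2[2],
              gs + 9L, gs + 67L)),
    strand = "+",
    type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS",
             "five_prime_UTR", "three_prime_UTR"),
    ID = c("gA", "gA.1", "gA.1.e1", "gA.1.e2", "gA.1.c1", "gA.1.c2",
           "gA.1.u5", "gA.1.u3"),
    Parent = c(NA, "gA", rep("gA.1", 6)),
    gene_id = "gA",
    phase = c(NA, NA, NA, NA, 0L, 0L, NA, NA))
  genome <- annotated_genome(
    Biostrings::DNAStringSet(c(chr1 = chrom_seq)), feats)
  # genomic position of CDS coordinate k
  cds_pos <- function(k) if (k <= 12L) gs + 10L + k - 1L
                         else gs + 46L + (k - 13L)
  list(genome = genome, cds_pos = cds_pos, gene_start = gs,
       intron = intron_iv, exon2 = exon2,
       chrom_seq = chrom_seq)
}

snp_at <- function(gpos, chrom_seq, alt) {
  variant_calls("chr1", gpos, substr(chrom_seq, gpos, gpos), alt,
                10L, 50L, "bubble")
}

test_that("each high-impact category is detected on the plus strand", {
  fx <- make_effect_genome()
  g <- fx$genome
  # TGG -> TGA: premature stop
  ef <- annotate_effects(snp_at(fx$cds_pos(6L), fx$chrom_seq, "A"), g)
  expect_equal(ef$category, "STOP_GAINED")
  # ATG -> GTG: start lost
  ef <- annotate_effects(snp_at(fx$cds_pos(1L), fx$chrom_seq, "G"), g)
  expect_equal(ef$category, "START_LOST")
  # terminal TAA -> TCA: stop lost
  ef <- annotate_effects(snp_at(fx$cds_pos(23L), fx$chrom_seq, "C"), g)
  expect_equal(ef$category, "STOP_LOST")
  # 1-bp insertion inside the CDS: frameshift
  ins <- variant_calls("chr1", fx$cds_pos(8L), "", "T", 10L, 50L, "bubble")
  expect_equal(annotate_effects(ins, g)$category, "FRAME_SHIFT")
  # codon-aligned 3-bp deletion of AAA (codon 3): no severe category
  p <- fx$cds_pos(7L)
  del3 <- variant_calls("chr1", p, substr(fx$chrom_seq, p, p + 2L), "",
                        10L, 50L, "bubble")
  expect_equal(annotate_effects(del3, g)$category, "NONE")
  # deletion covering all of exon 2: EXON_DELETED (beats the frameshift)
  del_ex <- variant_calls("chr1", fx$exon2[1] - 2L,
                          substr(fx$chrom_seq, fx$exon2[1] - 2L,
                                 fx$exon2[2] + 2L), "", 100L, 50L, "bubble")
  expect_equal(annotate_effects(del_ex, g)$category, "EXON_DELETED")
  # intron boundary SNPs: donor then acceptor
  ef <- annotate_effects(snp_at(fx$intron[1], fx$chrom_seq, "C"), g)
  expect_equal(ef$category, "SPLICE_SITE_DONOR")
  ef <- annotate_effects(snp_at(fx$intron[2], fx$chrom_seq, "C"), g)
  expect_equal(ef$category, "SPLICE_SITE_ACCEPTOR")
  # benign synonymous SNP: NONE (CCC -> CCA, both proline)
  ef <- annotate_effects(snp_at(fx$cds_pos(12L), fx$chrom_seq, "A"), g)
  expect_equal(ef$category, "NONE")
  # intergenic variant overlaps no gene: no rows
  ef <- annotate_effects(snp_at(10L, fx$chrom_seq, "C"), g)
  expect_equal(nrow(ef), 0L)
})

test_that("reverse-complementing the genome preserves all categories", {
  fx <- make_effect_genome()
  g <- fx$genome
  L <- nchar(fx$chrom_seq)
  rc_genome <- local({
    f <- g$features
    GenomicRanges::GRanges(
      "chr1",
      IRanges::IRanges(L - BiocGenerics::end(f) + 1L,
                       L - BiocGenerics::start(f) + 1L),
      strand = "-", type = f$type, ID = f$ID, Parent = f$Parent,
      gene_id = f$gene_id, phase = f$phase)
  })
  rc <- annotated_genome(
    Biostrings::DNAStringSet(c(chr1 = as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(fx$chrom_seq))))),
    rc_genome)
  rc_chr <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  mirror <- function(calls) {
    out <- calls
    for (i in seq_len(nrow(calls))) {
      r <- calls$ref[i]; a <- calls$alt[i]; p <- calls$pos[i]
      if (nchar(r) == 0L) {                # insertion between p-1 and p
        out$pos[i] <- L - p + 2L
        out$alt[i] <- rc_chr(a)
      } else {
        out$pos[i] <- L - (p + nchar(r) - 1L) + 1L
        out$ref[i] <- rc_chr(r)
        out$alt[i] <- if (nchar(a)) rc_chr(a) else ""
      }
    }
    out
  }
  probes <- list(
    snp_at(fx$cds_pos(6L), fx$chrom_seq, "A"),
    snp_at(fx$cds_pos(1L), fx$chrom_seq, "G"),
    snp_at(fx$cds_pos(23L), fx$chrom_seq, "C"),
    variant_calls("chr1", fx$cds_pos(8L), "", "T", 10L, 50L, "bubble"),
    variant_calls("chr1", fx$cds_pos(7L),
                  substr(fx$chrom_seq, fx$cds_pos(7L), fx$cds_pos(7L) + 2L),
                  "", 10L, 50L, "bubble"),
    snp_at(fx$intron[1], fx$chrom_seq, "C"),
    snp_at(fx$intron[2], fx$chrom_seq, "C"))
  for (v in probes) {
    fwd <- annotate_effects(v, g)$category
    rev <- annotate_effects(mirror(v), rc)$category
    expect_equal(rev, fwd, info = sprintf("pos %d ref '%s'", v$pos, v$ref))
  }
})

test_that("invalid reference CDS models are skipped with a warning", {
  fx <- make_effect_genome()
  f <- fx$genome$features
  # truncate one CDS by a base so the total is not a multiple of 3
  idx <- which(f$type == "CDS")[1]
  BiocGenerics::end(f)[idx] <- BiocGenerics::end(f)[idx] - 1L
  broken <- annotated_genome(fx$genome$seqs, f)
  v <- snp_at(fx$cds_pos(6L), fx$chrom_seq, "A")
  expect_warning(ef <- annotate_effects(v, broken), "multiple of 3")
  expect_equal(nrow(ef), 0L)
})

test_that("annotation agrees with the chromosome-level retranslation oracle", {
  sim <- cached_sim()
  ref <- sim$reference
  gt <- names(sim$genotypes)[1]
  calls <- truth_calls(sim, gt)
  ef <- annotate_effects(calls, ref)
  # oracle covers single-edit coding SNPs (the simulator keeps indels out of
  # exons); compare every variant that received a coding category or NONE
  cds_hits <- ef[ef$ref != "" & nchar(ef$ref) == 1L & nchar(ef$alt) == 1L, ]
  checked <- 0L
  for (i in seq_len(nrow(cds_hits))) {
    call <- cds_hits[i, c("chrom", "pos", "ref", "alt")]
    call$contig_length <- 10L; call$flank_quality <- 50L; call$caller <- "b"
    want <- oracle_effect(ref, call, cds_hits$gene_id[i])
    if (is.na(want)) next
    got <- cds_hits$category[i]
    if (got %in% c("SPLICE_SITE_DONOR", "SPLICE_SITE_ACCEPTOR")) next
    expect_equal(got, want,
                 info = sprintf("%s:%d %s>%s", call$chrom, call$pos,
                                call$ref, call$alt))
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})

test_that("affected genes are counted once regardless of effect count", {
  ef <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                   category = c("STOP_GAINED", "FRAME_SHIFT", "NONE",
                                "START_LOST"))
  expect_equal(count_affected_genes(ef), 2L)
  ef$genotype <- c("t", "t", "t", "r")
  out <- count_affected_genes(ef)
  expect_equal(out$affected_genes[out$genotype == "t"], 1L)
  expect_equal(out$affected_genes[out$genotype == "r"], 1L)
})
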