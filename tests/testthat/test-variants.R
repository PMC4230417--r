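test_that("quality filter keeps exactly the calls at or above the cutoff", {
  calls <- variant_calls(chrom = "chr1", pos = c(100L, 200L, 300L),
                         ref = "A", alt = "T", contig_length = 30L,
                         flank_quality = c(45L, 29L, 12L), caller = "bubble")
  kept <- filter_variants(calls)
  expect_equal(kept$flank_quality, 45L)
  # boundary: Q = 30 is not < 30, so it stays
  calls$flank_quality <- c(30L, 29L, 31L)
  expect_equal(filter_variants(calls)$flank_quality, c(30L, 31L))
  # empty in, empty out
  expect_equal(nrow(filter_variants(calls[0, ])), 0L)
})

test_that("overlapping calls merge to the longest assembled contig", {
  a <- variant_calls("chr1", 100L, "A", "G", 40L, 50L, "bubble")
  b <- variant_calls("chr1", 100L, "A", "G", 55L, 50L, "path_divergence")
  m <- merge_caller_outputs(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$contig_length, 55L)
  expect_equal(m$caller, "path_divergence")
  # same position on different chromosomes never overlaps
  b2 <- variant_calls("chr2", 100L, "A", "G", 55L, 50L, "path_divergence")
  expect_equal(nrow(merge_caller_outputs(a, b2)), 2L)
  # contig-interval overlap without equal positions also merges
  c1 <- variant_calls("chr1", 100L, "A", "G", 60L, 50L, "bubble")
  c2 <- variant_calls("chr1", 140L, "C", "T", 20L, 50L, "path_divergence")
  m2 <- merge_caller_outputs(c1, c2)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$pos, 100L)
  # ties on contig length keep the bubble caller's record
  t1 <- variant_calls("chr1", 100L, "A", "G", 50L, 50L, "path_divergence")
  t2 <- variant_calls("chr1", 100L, "A", "G", 50L, 50L, "bubble")
  expect_equal(merge_caller_outputs(t1, t2)$caller, "bubble")
})

test_that("merge is idempotent and ignores empty inputs", {
  set.seed(101)
  p <- random_caller_pair(30L, 0L)
  x <- merge_caller_outputs(p$a, p$a[0, ])
  expect_equal(nrow(x), nrow(oracle_merge(p$a, p$a[0, ])))
  xx <- merge_caller_outputs(x, x)
  expect_equal(xx[, c("chrom", "pos", "ref", "alt")],
               x[, c("chrom", "pos", "ref", "alt")])
})

test_that("merge matches the brute-force pairwise-overlap oracle", {
  set.seed(202)
  for (rep in 1:25) {
    p <- random_caller_pair(sample(10:50, 1), sample(10:50, 1))
    got <- merge_caller_outputs(p$a, p$b)
    want <- oracle_merge(p$a, p$b)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$pos, want$pos)
    expect_equal(got$contig_length, want$contig_length)
    expect_equal(got$caller, want$caller)
  }
})

test_that("applying variants edits sequence and length as defined", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  snp <- variant_calls("chr1", 3L, "G", "T", 10L, 50L, "bubble")
  res <- apply_variants(ref, snp)
  expect_equal(as.character(res$seqs[["chr1"]]), "ACTTACGT")
  # length arithmetic: one 2-bp deletion plus one 5-bp insertion on 100 bp
  set.seed(1)
  ref2 <- Biostrings::DNAStringSet(c(chr1 = rand_dna_str(100L)))
  r <- as.character(ref2[[1]])
  calls <- variant_calls(chrom = "chr1", pos = c(20L, 60L),
                         ref = c(substr(r, 20, 21), ""),
                         alt = c("", "TTTTT"),
                         contig_length = c(10L, 10L),
                         flank_quality = 50L, caller = "bubble")
  res2 <- apply_variants(ref2, calls)
  expect_equal(nchar(as.character(res2$seqs[[1]])), 103L)
  # position 90 lifts by the cumulative offset -2 + 5
  expect_equal(lift_positions(res2$map, "chr1", 90L), 93L)
  # positions before any indel are unmoved
  expect_equal(lift_positions(res2$map, "chr1", 10L), 10L)
})

test_that("reference mismatches and overlaps are rejected with coordinates", {
  ref <- Biostrings::DNAStringSet(c(chr7 = "ACGTACGTACGT"))
  bad <- variant_calls("chr7", 3L, "T", "A", 10L, 50L, "bubble")
  expect_error(apply_variants(ref, bad), "chr7.*position 3")
  ov <- variant_calls(chrom = "chr7", pos = c(2L, 4L),
                      ref = c("CGTA", "TACG"), alt = c("", ""),
                      contig_length = 10L, flank_quality = 50L,
                      caller = "bubble")
  expect_error(apply_variants(ref, ov), "overlapping")
  unk <- variant_calls("chrX", 1L, "A", "T", 5L, 50L, "bubble")
  expect_error(apply_variants(ref, unk), "unknown chromosome")
})

test_that("random indels match the sequential string-edit oracle", {
  set.seed(303)
  L <- 50000L
  refchr <- rand_dna_str(L)
  ref <- Biostrings::DNAStringSet(c(chr1 = refchr))
  # 200 non-overlapping random indels/SNPs
  pos <- sort(sample(seq(10L, L - 20L), 400L))
  pos <- pos[c(TRUE, diff(pos) > 15L)][1:200]
  kind <- sample(c("snp", "ins", "del"), length(pos), replace = TRUE)
  ref_al <- ifelse(kind == "snp", substring(refchr, pos, pos),
            ifelse(kind == "del",
                   substring(refchr, pos, pos + 3L), ""))
  alt_al <- ifelse(kind == "snp", "A",
            ifelse(kind == "del", "", "GATTA"))
  swap <- kind == "snp" & ref_al == "A"
  alt_al[swap] <- "C"
  calls <- variant_calls(chrom = "chr1", pos = pos, ref = ref_al,
                         alt = alt_al,
                         contig_length = pmax(nchar(ref_al), nchar(alt_al)) + 5L,
                         flank_quality = 50L, caller = "bubble")
  res <- apply_variants(ref, calls)
  expect_equal(as.character(res$seqs[[1]]), oracle_apply_chrom(refchr, calls))
})

test_that("liftover round-trips every non-variant position", {
  sim <- cached_sim()
  gt <- names(sim$genotypes)[1]
  calls <- truth_calls(sim, gt)
  res <- apply_variants(sim$reference, calls)
  inv <- invert_coordinate_map(res$map)
  L <- lengths(sim$reference$seqs)[[1]]
  chrom <- names(sim$reference$seqs)[1]
  x <- calls[calls$chrom == chrom, ]
  in_span <- unlist(mapply(function(p, r) if (nchar(r)) p:(p + nchar(r) - 1L)
                           else integer(0), x$pos, x$ref))
  outside <- setdiff(seq_len(L), in_span)
  fwd <- lift_positions(res$map, chrom, outside)
  expect_false(anyNA(fwd))
  back <- lift_positions(inv, chrom, fwd)
  expect_equal(back, outside)
})

test_that("region classification follows the EXON>UTR>INTRON precedence", {
  sim <- cached_sim()
  ref <- sim$reference
  f <- ref$features
  cds1 <- f[f$type == "CDS"][1]
  gid <- cds1$gene_id
  sg <- unname(ref$subgenome[gid])
  p <- BiocGenerics::start(cds1) + 1L
  chrom <- as.character(GenomeInfoDb::seqnames(cds1))
  base <- substr(as.character(ref$seqs[[chrom]]), p, p)
  calls <- variant_calls(chrom, p, base, setdiff(c("A", "C"), base)[1],
                         10L, 50L, "bubble")
  rc <- classify_regions(calls, ref)
  expect_equal(rc$count[rc$region == "EXON" & rc$subgenome == sg], 1L)
  expect_equal(rc$length[rc$region == "EXON" & rc$subgenome == sg], 1L)
  expect_equal(sum(rc$count), 1L)
  # unknown chromosome errors
  expect_error(classify_regions(
    variant_calls("nope", 1L, "A", "T", 5L, 50L, "x"), ref),
    "unknown chromosome")
})

test_that("region counts match the per-base oracle and conserve totals", {
  sim <- cached_sim()
  ref <- sim$reference
  gt <- names(sim$genotypes)[1]
  calls <- truth_calls(sim, gt)
  rc <- classify_regions(calls, ref)
  expect_equal(sum(rc$count), nrow(calls))
  asn <- attr(rc, "assignments")
  set.seed(7)
  idx <- sample(nrow(calls), 60L)
  for (i in idx) {
    want <- oracle_region_of(ref, calls$chrom[i], calls$pos[i])
    expect_equal(asn$region[i], want$region,
                 info = sprintf("pos %d", calls$pos[i]))
    if (!is.na(want$gene))
      expect_equal(asn$subgenome[i], unname(ref$subgenome[want$gene]))
  }
  expect_equal(asn$length, pmax(nchar(calls$ref), nchar(calls$alt), 1L))
})
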