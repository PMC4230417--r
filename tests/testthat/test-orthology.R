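random_proteins <- function(n, len_range = c(60L, 120L), prefix = "p") {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = ""), character(1))
  Biostrings::AAStringSet(setNames(seqs, paste0(prefix, seq_len(n))))
}

mutate_protein_chr <- function(p, k) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(p, "")[[1]]
  idx <- sample(length(ch), min(k, length(ch)))
  for (i in idx) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}

test_that("identical sequences score symmetrically at full identity", {
  set.seed(1)
  p <- as.character(random_proteins(1, c(100L, 100L))[[1]])
  hit <- score_similarity(p, p)
  expect_equal(hit$identity, 1)
  expect_equal(hit$score, oracle_sw_score(p, p))
  # symmetry on distinct sequences
  q <- mutate_protein_chr(p, 10L)
  expect_equal(score_similarity(p, q)$score, score_similarity(q, p)$score)
  # invalid residues are refused
  expect_error(score_similarity("MKV1", "MKV"), "invalid residue")
  expect_error(score_similarity("", "MKV"), "validation error")
})

test_that("alignment scores match the independent dynamic-programming oracle", {
  set.seed(2)
  for (rep in 1:20) {
    a <- as.character(random_proteins(1, c(40L, 150L))[[1]])
    b <- if (rep %% 2 == 0) mutate_protein_chr(a, sample(1:30, 1))
         else as.character(random_proteins(1, c(40L, 150L))[[1]])
    expect_equal(score_similarity(a, b)$score, oracle_sw_score(a, b),
                 info = sprintf("rep %d", rep))
  }
})

test_that("unrelated random sequences stay near background", {
  set.seed(3)
  a <- random_proteins(1, c(80L, 80L))
  b <- random_proteins(1, c(80L, 80L), prefix = "q")
  hit <- score_similarity(as.character(a[[1]]), as.character(b[[1]]))
  expect_lt(hit$score, 50)
  expect_lt(hit$identity, 0.6)
})

test_that("a duplicated proteome pairs every gene with its duplicate", {
  set.seed(4)
  A <- random_proteins(12L)
  B <- A
  names(B) <- paste0("dup_", names(A))
  rbh <- reciprocal_best_hits(A, B)
  expect_equal(nrow(rbh), 12L)
  expect_equal(rbh$gene_b, paste0("dup_", rbh$gene_a))
})

test_that("scores below the floor leave genes unpaired", {
  set.seed(5)
  A <- random_proteins(4L, c(30L, 40L))
  B <- random_proteins(4L, c(30L, 40L), prefix = "q")
  rbh <- reciprocal_best_hits(A, B, score_floor = 200)
  expect_equal(nrow(rbh), 0L)
})

test_that("ties for best hit break the pairing", {
  A <- Biostrings::AAStringSet(c(a1 = "MKVLWAALLVTFLAGCQA"))
  B <- Biostrings::AAStringSet(c(b1 = "MKVLWAALLVTFLAGCQA",
                                 b2 = "MKVLWAALLVTFLAGCQA"))
  expect_equal(nrow(reciprocal_best_hits(A, B, score_floor = 10)), 0L)
})

test_that("RBH on planted homologs matches the exhaustive oracle", {
  set.seed(6)
  A <- random_proteins(30L, c(60L, 100L))
  # 20 homologs with drift + 10 unrelated
  bseqs <- c(vapply(as.character(A)[1:20], mutate_protein_chr, "", k = 8L),
             as.character(random_proteins(10L, c(60L, 100L), prefix = "x")))
  B <- Biostrings::AAStringSet(setNames(bseqs, paste0("b", 1:30)))
  scores <- similarity_matrix(A, B)
  oracle_scores <- oracle_sw_matrix(A, B)
  expect_equal(unname(scores), unname(oracle_scores))
  got <- reciprocal_best_hits(A, B, scores = scores)
  want <- oracle_rbh(oracle_scores)
  got <- got[order(got$gene_a), ]; want <- want[order(want$gene_a), ]
  expect_equal(got$gene_a, want$gene_a)
  expect_equal(got$gene_b, want$gene_b)
  expect_equal(got$score, want$score)
})

test_that("RBH is symmetric under swapping the proteomes", {
  set.seed(7)
  A <- random_proteins(15L)
  bseqs <- vapply(as.character(A)[1:10], mutate_protein_chr, "", k = 5L)
  B <- Biostrings::AAStringSet(setNames(bseqs, paste0("b", 1:10)))
  ab <- reciprocal_best_hits(A, B)
  ba <- reciprocal_best_hits(B, A)
  expect_equal(ab[order(ab$gene_a), c("gene_a", "gene_b")],
               setNames(ba[order(ba$gene_b), c("gene_b", "gene_a")],
                        c("gene_a", "gene_b")),
               ignore_attr = TRUE)
})

test_that("positional orthology keeps same-chromosome pairs only", {
  sim <- cached_sim()
  ort <- sim_orthology(sim)
  # the filter never adds pairs
  prot_a <- ort$proteomes[[1]]; prot_b <- ort$proteomes[[2]]
  rbh <- reciprocal_best_hits(prot_a, prot_b)
  expect_lte(nrow(ort$ab), nrow(rbh))
  expect_true(all(paste(ort$ab$gene_a, ort$ab$gene_b) %in%
                    paste(rbh$gene_a, rbh$gene_b)))
  ta <- gene_table(ort$genomes[[1]]); tb <- gene_table(ort$genomes[[2]])
  expect_true(all(ta$chrom[match(ort$ab$gene_a, ta$gene_id)] ==
                    tb$chrom[match(ort$ab$gene_b, tb$gene_id)]))
  # a cross-chromosome RBH pair is excluded
  g2 <- ort$genomes[[2]]
  moved <- gene_table(g2)$gene_id[1]
  f <- g2$features
  lv <- unique(c(as.character(GenomeInfoDb::seqnames(f)), "A99"))
  GenomeInfoDb::seqlevels(f) <- lv
  sel <- f$gene_id == moved
  fd <- f[sel]
  GenomeInfoDb::seqnames(fd) <- factor("A99", levels = lv)
  f <- c(f[!sel], fd)
  seqs2 <- c(g2$seqs, setNames(Biostrings::DNAStringSet("ACGT"), "A99"))
  g2m <- annotated_genome(seqs2, f, g2$subgenome)
  pm <- positional_orthologs(ort$genomes[[1]], g2m,
                             proteome_a = prot_a, proteome_b = prot_b)
  expect_false(moved %in% pm$gene_b)
  # empty genome gives an empty table
  empty <- annotated_genome(
    Biostrings::DNAStringSet(c(A01 = "ACGTACGT")),
    GenomicRanges::GRanges(seqnames = factor(levels = "A01"),
                           type = character(), ID = character(),
                           Parent = character(), gene_id = character(),
                           phase = integer()))
  expect_equal(nrow(positional_orthologs(empty, ort$genomes[[1]])), 0L)
})

test_that("copy counts recover the simulated family structure exactly", {
  sim <- cached_sim("noise_free", function()
    simulate_pangenome(noise_free_config(seed = 31L)))
  cc <- sim_copy_counts(sim)
  truth <- sim$truth$copy_counts
  m <- merge(cc, truth, by = c("outgroup", "outgroup_gene", "genome"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$count.x, m$count.y)
  # an outgroup gene unrelated to every genome gene counts zero
  og <- sim$outgroups[[1]]
  set.seed(8)
  stray <- random_proteins(1, c(70L, 70L), prefix = "stray")
  og2 <- c(og, stray)
  cc2 <- ortholog_copy_counts(og2, extract_proteins(sim$reference))
  expect_equal(cc2$count[cc2$outgroup_gene == "stray1"], 0L)
})
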