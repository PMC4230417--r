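test_that("invalid configurations are rejected", {
  expect_error(simulation_config(snp_rate = 1.5), "configuration error")
  expect_error(simulation_config(gene_loss_prob = -0.1), "configuration error")
  expect_error(simulation_config(chromosome_length = 500), "configuration error")
  expect_error(simulation_config(subgenome_labels = c("LF", "MF1")),
               "configuration error")
  expect_error(simulation_config(subgenome_labels = c("LF", "LF", "MF2")),
               "configuration error")
})

test_that("identical seeds reproduce identical outputs byte for byte", {
  cfg <- simulation_config(n_chromosomes = 1L, chromosome_length = 30000L,
                           n_genes_per_subgenome = 4L, seed = 11L)
  s1 <- simulate_pangenome(cfg)
  s2 <- simulate_pangenome(cfg)
  expect_identical(as.character(s1$reference$seqs),
                   as.character(s2$reference$seqs))
  expect_identical(s1$truth$variants, s2$truth$variants)
  expect_identical(s1$caller_outputs, s2$caller_outputs)
  expect_identical(lapply(s1$outgroups, as.character),
                   lapply(s2$outgroups, as.character))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_inputs(s1, d1); write_inputs(s2, d2)
  files <- list.files(d1, recursive = TRUE)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("applying the true variants reproduces each genotype exactly", {
  sim <- cached_sim()
  for (gt in names(sim$genotypes)) {
    res <- apply_variants(sim$reference, truth_calls(sim, gt))
    expect_identical(as.character(res$seqs),
                     as.character(sim$genotypes[[gt]]$seqs))
  }
})

test_that("realized SNP density matches the configured rate (binomial test)", {
  cfg <- simulation_config(n_chromosomes = 1L, chromosome_length = 500000L,
                           n_genes_per_subgenome = 10L, indel_rate = 0,
                           gene_loss_prob = 0, gene_dup_prob = 0, seed = 5L)
  sim <- simulate_pangenome(cfg)
  for (gt in names(sim$genotypes)) {
    n <- nrow(sim$truth$variants[[gt]])
    pt <- stats::binom.test(n, cfg$chromosome_length, p = cfg$snp_rate)
    expect_gt(pt$p.value, 0.001)
  }
})

test_that("without differentiating events every gene is common", {
  cfg <- simulation_config(n_chromosomes = 1L, chromosome_length = 40000L,
                           n_genes_per_subgenome = 5L, gene_loss_prob = 0,
                           gene_dup_prob = 0, caller_miss_prob = 0, seed = 2L)
  sim <- simulate_pangenome(cfg)
  expect_true(all(sim$truth$pan_class$class == "common"))
})

test_that("truth tables are internally consistent", {
  sim <- cached_sim()
  tr <- sim$truth
  # one class per gene per genome
  expect_false(anyDuplicated(tr$pan_class[, c("genome", "gene_id")]) > 0)
  # copy counts are non-negative integers
  expect_true(all(tr$copy_counts$count >= 0L))
  # variant positions sorted and non-overlapping within a chromosome
  for (gt in names(tr$variants)) {
    v <- tr$variants[[gt]]
    for (ch in unique(v$chrom)) {
      x <- v[v$chrom == ch, ]
      expect_true(all(diff(x$pos) > 0))
      ends <- x$pos + pmax(nchar(x$ref), 1L) - 1L
      expect_true(all(utils::head(ends, -1) < utils::tail(x$pos, -1)))
    }
  }
  # every genotype gene has exactly one pan class and a subgenome label
  for (gt in names(sim$genotypes)) {
    gids <- gene_table(sim$genotypes[[gt]])$gene_id
    cls <- tr$pan_class[tr$pan_class$genome == gt, ]
    expect_setequal(cls$gene_id, gids)
    sg <- tr$subgenome[tr$subgenome$genome == gt, ]
    expect_setequal(sg$gene_id, gids)
    expect_true(all(sg$label %in% sim$config$subgenome_labels))
  }
})

test_that("the two caller outputs jointly cover all true variants", {
  cfg <- tiny_config(seed = 9L, caller_miss_prob = 0.2)
  sim <- simulate_pangenome(cfg)
  for (gt in names(sim$genotypes)) {
    tv <- sim$truth$variants[[gt]]
    reported <- unique(rbind(
      sim$caller_outputs[[gt]]$bubble[, c("chrom", "pos", "ref", "alt")],
      sim$caller_outputs[[gt]]$path_divergence[, c("chrom", "pos", "ref", "alt")]))
    expect_equal(nrow(merge(tv[, c("chrom", "pos", "ref", "alt")], reported)),
                 nrow(tv))
  }
})

test_that("write_inputs emits a complete, re-parsable file set", {
  sim <- cached_sim()
  dir <- withr::local_tempdir()
  man <- write_inputs(sim, dir)
  # 2 genotypes x 2 callers -> 4 VCFs
  expect_equal(sum(grepl("^calls_.*\\.vcf$", man$file)), 4L)
  expect_true(all(file.exists(file.path(dir, man$file))))
  # manifest counts match the in-memory objects
  expect_equal(man$records[man$file == "reference.gff3"],
               length(sim$reference$features))
  expect_equal(man$records[man$file == "calls_turnip_bubble.vcf"],
               nrow(sim$caller_outputs$turnip$bubble))
  # GFF3 round trip preserves the gene models
  g2 <- read_gff3(file.path(dir, "reference.gff3"))
  f1 <- sim$reference$features
  expect_equal(length(g2), length(f1))
  o1 <- order(f1$ID, f1$type, BiocGenerics::start(f1))
  o2 <- order(g2$ID, g2$type, BiocGenerics::start(g2))
  expect_equal(BiocGenerics::start(g2)[o2], BiocGenerics::start(f1)[o1])
  expect_equal(BiocGenerics::end(g2)[o2], BiocGenerics::end(f1)[o1])
  expect_equal(g2$gene_id[o2], f1$gene_id[o1])
  expect_equal(as.character(BiocGenerics::strand(g2))[o2],
               as.character(BiocGenerics::strand(f1))[o1])
  # unwritable directory -> I/O error
  ro <- file.path(dir, "ro")
  dir.create(ro, mode = "0500")
  if (file.access(ro, 2L) != 0L)
    expect_error(write_inputs(sim, file.path(ro, "sub")), "I/O error")
})

test_that("gene architecture is well-formed", {
  sim <- cached_sim()
  ref <- sim$reference
  gt <- gene_table(ref)
  prots <- extract_proteins(ref)
  expect_equal(length(prots), nrow(gt))
  # every CDS translates to a protein starting with M and free of stops
  expect_true(all(substr(as.character(prots), 1, 1) == "M"))
  expect_false(any(grepl("*", as.character(prots), fixed = TRUE)))
  # introns start GT and end AG in transcription direction
  f <- ref$features
  for (g in utils::head(gt$gene_id, 10)) {
    ex <- f[f$type == "exon" & f$gene_id == g]
    if (length(ex) < 2) next
    es <- sort(BiocGenerics::start(ex)); ee <- sort(BiocGenerics::end(ex))
    chrom <- as.character(ref$seqs[[gt$chrom[gt$gene_id == g]]])
    plus <- gt$strand[gt$gene_id == g] == "+"
    for (k in seq_len(length(es) - 1)) {
      left <- substr(chrom, ee[k] + 1, ee[k] + 2)
      right <- substr(chrom, es[k + 1] - 2, es[k + 1] - 1)
      if (plus) {
        expect_equal(left, "GT"); expect_equal(right, "AG")
      } else {
        expect_equal(left, "CT"); expect_equal(right, "AC")
      }
    }
  }
})
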