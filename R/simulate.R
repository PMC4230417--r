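#' Simulation configuration
#'
#' Parameters for the pan-genome simulator. The simulated genome is
#' triplicated: every chromosome carries one contiguous block per subgenome
#' (LF, MF1, MF2), emulating the fractionated subgenomes of a mesopolyploid
#' Brassica-type genome. Gene families carry 1, 2 or 3 copies spread over the
#' subgenomes, so ortholog copy counts against the outgroup proteomes are
#' known by construction. Two genotypes are derived from the reference by
#' SNPs, short indels, whole-gene losses and tandem gene duplications; their
#' true variants are reported by two noisy callers ("bubble" and
#' "path_divergence").
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in bp (>= 1000).
#' @param n_genes_per_subgenome Gene slots per subgenome (whole genome).
#' @param subgenome_labels Exactly three subgenome labels.
#' @param snp_rate Per-bp SNP rate of each genotype versus the reference
#'   (default 0.0045, i.e. 0.45 differences per 100 bp).
#' @param indel_rate Per-bp short-indel rate versus the reference.
#' @param indel_max_len Maximum short-indel length in bp.
#' @param gene_loss_prob Probability that a genotype loses a given gene.
#' @param gene_dup_prob Probability that a genotype tandem-duplicates a gene.
#' @param caller_miss_prob Probability a true variant is reported by only one
#'   of the two callers.
#' @param low_quality_prob Probability a reported call receives a 5'-flank
#'   mapping quality below 30.
#' @param copy_class_probs Probabilities that a gene family has 1, 2 or 3
#'   subgenome copies.
#' @param longer_contig_frac Fraction of shared sites where the
#'   path-divergence caller assembles a longer contig than the bubble caller.
#' @param paralog_divergence Per-bp divergence between subgenome copies of a
#'   family (stop-codon-safe point substitutions).
#' @param outgroup_divergence Per-residue divergence of each outgroup protein
#'   from the family consensus (one value per outgroup).
#' @param cds_codons_range,n_exons_range,intron_len_range,utr_len_range Gene
#'   architecture ranges (codons incl. start/stop; exon count; intron and UTR
#'   lengths in bp).
#' @param reference_name,genotype_names,outgroup_names Genome/outgroup names.
#' @param seed Integer RNG seed; a fixed seed reproduces all outputs exactly.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 2L,
                              chromosome_length = 150000L,
                              n_genes_per_subgenome = 30L,
                              subgenome_labels = c("LF", "MF1", "MF2"),
                              snp_rate = 0.0045,
                              indel_rate = 4e-4,
                              indel_max_len = 10L,
                              gene_loss_prob = 0.03,
                              gene_dup_prob = 0.02,
                              caller_miss_prob = 0.05,
                              low_quality_prob = 0.02,
                              copy_class_probs = c(0.6, 0.25, 0.15),
                              longer_contig_frac = 0.5,
                              paralog_divergence = 0.03,
                              outgroup_divergence = c(0.04, 0.07),
                              cds_codons_range = c(50L, 90L),
                              n_exons_range = c(1L, 3L),
                              intron_len_range = c(60L, 120L),
                              utr_len_range = c(30L, 80L),
                              reference_name = "chiifu",
                              genotype_names = c("turnip", "rapid_cycling"),
                              outgroup_names = c("arabidopsis_like",
                                                 "thellungiella_like"),
                              seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes_per_subgenome = as.integer(n_genes_per_subgenome),
              subgenome_labels = as.character(subgenome_labels),
              snp_rate = snp_rate, indel_rate = indel_rate,
              indel_max_len = as.integer(indel_max_len),
              gene_loss_prob = gene_loss_prob, gene_dup_prob = gene_dup_prob,
              caller_miss_prob = caller_miss_prob,
              low_quality_prob = low_quality_prob,
              copy_class_probs = copy_class_probs / sum(copy_class_probs),
              longer_contig_frac = longer_contig_frac,
              paralog_divergence = paralog_divergence,
              outgroup_divergence = outgroup_divergence,
              cds_codons_range = as.integer(cds_codons_range),
              n_exons_range = as.integer(n_exons_range),
              intron_len_range = as.integer(intron_len_range),
              utr_len_range = as.integer(utr_len_range),
              reference_name = reference_name,
              genotype_names = as.character(genotype_names),
              outgroup_names = as.character(outgroup_names),
              seed = as.integer(seed))
  rates <- c(cfg$snp_rate, cfg$indel_rate, cfg$gene_loss_prob,
             cfg$gene_dup_prob, cfg$caller_miss_prob, cfg$low_quality_prob,
             cfg$longer_contig_frac, cfg$paralog_divergence,
             cfg$outgroup_divergence)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("configuration error: all rates and probabilities must lie in [0, 1]")
  if (cfg$chromosome_length < 1000L)
    stop("configuration error: chromosome_length must be >= 1000")
  if (length(cfg$subgenome_labels) != 3L ||
      anyDuplicated(cfg$subgenome_labels))
    stop("configuration error: exactly three distinct subgenome labels required")
  if (length(cfg$genotype_names) != 2L)
    stop("configuration error: exactly two derived genotypes are simulated")
  if (length(cfg$outgroup_names) != length(cfg$outgroup_divergence))
    stop("configuration error: one outgroup_divergence per outgroup")
  class(cfg) <- "simulation_config"
  cfg
}

# ---- sequence helpers ------------------------------------------------------

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# random CDS: ATG + non-stop codons + TAA
rand_cds <- function(n_codons) {
  codons <- character(n_codons - 2L)
  i <- 1L
  while (i <= length(codons)) {
    cd <- rand_dna(3L)
    if (!cd %in% .STOPS) { codons[i] <- cd; i <- i + 1L }
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

codon_at <- function(chars, cds_pos) {
  c0 <- ((cds_pos - 1L) %/% 3L) * 3L + 1L
  paste(chars[c0:(c0 + 2L)], collapse = "")
}

# point-substitute a CDS with a fixed number of changes (rate x length),
# never touching the start/stop codons and never creating a premature stop.
# The deterministic change count keeps within-family alignment-score spread
# narrow, so family copy counts stay recoverable at the inclusion ratio.
mutate_cds <- function(cds, rate) {
  chars <- strsplit(cds, "")[[1]]
  n <- length(chars)
  if (n < 10L) return(cds)
  n_mut <- max(2L, round(rate * (n - 6L)))
  hit <- sample(4:(n - 3L), min(n_mut, n - 6L))
  for (p in hit) {
    for (b in sample(setdiff(.BASES, chars[p]))) {
      old <- chars[p]; chars[p] <- b
      if (codon_at(chars, p) %in% .STOPS) chars[p] <- old else break
    }
  }
  paste(chars, collapse = "")
}

# n_changes guaranteed-nonsynonymous substitutions inside internal codons
mutate_cds_nonsyn <- function(cds, n_changes) {
  chars <- strsplit(cds, "")[[1]]
  n_codons <- length(chars) %/% 3L
  done <- 0L; guard <- 0L
  while (done < n_changes && guard < 200L) {
    guard <- guard + 1L
    cod <- sample(2:(n_codons - 1L), 1L)
    off <- sample(1:2, 1L)                 # first two codon positions
    p <- (cod - 1L) * 3L + off
    old <- chars[p]
    b <- sample(setdiff(.BASES, old), 1L)
    chars[p] <- b
    newcod <- codon_at(chars, p)
    oldchars <- chars; oldchars[p] <- old
    if (newcod %in% .STOPS ||
        translate_chr(newcod) == translate_chr(codon_at(oldchars, p))) {
      chars[p] <- old
    } else done <- done + 1L
  }
  paste(chars, collapse = "")
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# per-chromosome lookup: for every CDS base, its gene index and spliced-CDS
# coordinate; used to draw stop-codon-safe coding SNPs
build_cds_context <- function(genome, chrom, cds_all = NULL) {
  L <- nchar(as.character(genome$seqs[[chrom]]))
  cds <- cds_table(genome)
  cds <- cds[cds$chrom == chrom, , drop = FALSE]
  genes <- unique(cds$gene_id)
  gene_of <- integer(L); coord <- integer(L)
  if (is.null(cds_all)) cds_all <- spliced_cds_all(genome)
  cds_seq <- unname(cds_all[genes])
  strand <- character(length(genes))
  for (gi in seq_along(genes)) {
    iv <- cds[cds$gene_id == genes[gi], , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    minus <- iv$strand[1] == "-"
    if (minus) iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
    strand[gi] <- iv$strand[1]
    off <- 0L
    for (r in seq_len(nrow(iv))) {
      len <- iv$end[r] - iv$start[r] + 1L
      posv <- iv$start[r]:iv$end[r]
      coord[posv] <- if (minus) off + rev(seq_len(len)) else off + seq_len(len)
      gene_of[posv] <- gi
      off <- off + len
    }
  }
  list(gene_of = gene_of, coord = coord, cds = cds_seq, strand = strand)
}

# alternative base for a SNP at p: outside CDS any other base; inside CDS a
# base that neither creates a stop codon nor touches the start/stop codon
# (fixed nonsense differences are not tolerated between viable inbred lines)
choose_snp_alt <- function(ctx, refchr, p) {
  rb <- substr(refchr, p, p)
  gi <- ctx$gene_of[p]
  if (gi == 0L) return(sample(setdiff(.BASES, rb), 1L))
  cc <- ctx$coord[p]
  cds <- ctx$cds[gi]
  ncod <- nchar(cds) %/% 3L
  k <- (cc - 1L) %/% 3L + 1L
  if (k == 1L || k == ncod) return(NA_character_)
  cod_start <- (k - 1L) * 3L
  codon <- substr(cds, cod_start + 1L, cod_start + 3L)
  within <- cc - cod_start
  for (b in sample(setdiff(.BASES, rb))) {
    cb <- if (ctx$strand[gi] == "-") .COMP[[b]] else b
    nc <- codon
    substr(nc, within, within) <- cb
    if (!nc %in% .STOPS) return(b)
  }
  NA_character_
}

# fixed-count residue substitution (rate x length changes)
mutate_protein <- function(aa, rate) {
  chars <- strsplit(aa, "")[[1]]
  n_mut <- max(2L, round(rate * length(chars)))
  hit <- sample(length(chars), min(n_mut, length(chars)))
  for (p in hit) chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
  paste(chars, collapse = "")
}

# ---- gene architecture -----------------------------------------------------

# Build one gene's genomic sequence and relative features (1-based within the
# gene). CDS is split over `n_exons` exons; introns start GT and end AG.
build_gene <- function(cds, n_exons, intron_lens, utr5_len, utr3_len, strand) {
  cds_len <- nchar(cds)
  stopifnot(cds_len %% 3L == 0L)
  # split CDS into n_exons chunks of >= 3 bp
  if (n_exons == 1L) {
    chunks <- cds_len
  } else {
    cuts <- sort(sample(seq(3L, cds_len - 3L, by = 3L), n_exons - 1L))
    chunks <- diff(c(0L, cuts, cds_len))
  }
  utr5 <- rand_dna(utr5_len); utr3 <- rand_dna(utr3_len)
  introns <- vapply(intron_lens, function(l)
    paste0("GT", rand_dna(l - 4L), "AG"), character(1))
  # assemble plus-strand layout and record intervals
  seq_parts <- character(0)
  feats <- list()
  cursor <- 0L
  cds_off <- 0L
  add <- function(s) { seq_parts[[length(seq_parts) + 1L]] <<- s; cursor <<- cursor + nchar(s) }
  exon_iv <- list(); cds_iv <- list(); phases <- integer(0)
  utr5_iv <- NULL; utr3_iv <- NULL
  for (i in seq_len(n_exons)) {
    ex_start <- cursor + 1L
    if (i == 1L) { utr5_iv <- c(ex_start, cursor + utr5_len); add(utr5) }
    cds_start <- cursor + 1L
    add(substr(cds, cds_off + 1L, cds_off + chunks[i]))
    phases <- c(phases, (3L - cds_off %% 3L) %% 3L)
    cds_iv[[i]] <- c(cds_start, cursor)
    cds_off <- cds_off + chunks[i]
    if (i == n_exons) { utr3_iv <- c(cursor + 1L, cursor + utr3_len); add(utr3) }
    exon_iv[[i]] <- c(ex_start, cursor)
    if (i < n_exons) add(introns[i])
  }
  total <- cursor
  seq <- paste(seq_parts, collapse = "")
  rows <- list(data.frame(type = "gene", start = 1L, end = total,
                          phase = NA_integer_),
               data.frame(type = "mRNA", start = 1L, end = total,
                          phase = NA_integer_))
  for (iv in exon_iv)
    rows[[length(rows) + 1L]] <- data.frame(type = "exon", start = iv[1],
                                            end = iv[2], phase = NA_integer_)
  for (i in seq_along(cds_iv))
    rows[[length(rows) + 1L]] <- data.frame(type = "CDS",
                                            start = cds_iv[[i]][1],
                                            end = cds_iv[[i]][2],
                                            phase = phases[i])
  if (utr5_len > 0L)
    rows[[length(rows) + 1L]] <- data.frame(type = "five_prime_UTR",
                                            start = utr5_iv[1], end = utr5_iv[2],
                                            phase = NA_integer_)
  if (utr3_len > 0L)
    rows[[length(rows) + 1L]] <- data.frame(type = "three_prime_UTR",
                                            start = utr3_iv[1], end = utr3_iv[2],
                                            phase = NA_integer_)
  feats <- do.call(rbind, rows)
  if (strand == "-") {
    seq <- revcomp_chr(seq)
    new_start <- total - feats$end + 1L
    new_end <- total - feats$start + 1L
    feats$start <- new_start; feats$end <- new_end
  }
  feats$strand <- strand
  feats <- feats[order(feats$start, match(feats$type,
            c("gene", "mRNA", "exon", "CDS", "five_prime_UTR",
              "three_prime_UTR"))), , drop = FALSE]
  list(seq = seq, feats = feats, length = total)
}

max_gene_length <- function(cfg) {
  3L * cfg$cds_codons_range[2] +
    (cfg$n_exons_range[2] - 1L) * cfg$intron_len_range[2] +
    2L * cfg$utr_len_range[2]
}

# ---- main simulator --------------------------------------------------------

#' Simulate a pan-genome with known truth
#'
#' Generates a triplicated, annotated reference genome, two derived genotypes
#' with recorded variant and gene gain/loss events, two noisy caller outputs
#' per genotype, and outgroup proteomes with known per-family copy counts.
#' All downstream pipeline stages can be validated against the returned
#' truth tables. A fixed seed reproduces every output byte-for-byte.
#'
#' @param config A [simulation_config()].
#' @return A list of class `pangenome_sim` with elements `reference`,
#'   `genotypes` (named list of `annotated_genome`), `caller_outputs` (per
#'   genotype, per caller variant-call data.frames), `outgroups` (named list
#'   of `AAStringSet`), `truth` (see below) and `config`. `truth` contains
#'   `variants` (per genotype), `ortholog_map`, `pan_class`, `subgenome` and
#'   `copy_counts`.
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  labels <- cfg$subgenome_labels
  n_chr <- cfg$n_chromosomes
  L <- cfg$chromosome_length
  chroms <- sprintf("A%02d", seq_len(n_chr))

  # -- gene families over subgenome slots ------------------------------------
  cap <- setNames(rep(cfg$n_genes_per_subgenome, 3L), labels)
  fam_members <- list()   # family -> label vector
  while (sum(cap) > 0L) {
    kmax <- sum(cap > 0L)
    pr <- cfg$copy_class_probs[seq_len(kmax)]
    k <- sample.int(kmax, 1L, prob = pr / sum(pr))
    # prefer the subgenomes with most remaining capacity, random among ties
    ord <- order(-cap, runif(3L))
    chosen <- labels[ord][seq_len(k)]
    chosen <- chosen[cap[chosen] > 0L]
    cap[chosen] <- cap[chosen] - 1L
    fam_members[[length(fam_members) + 1L]] <- chosen
  }
  n_fam <- length(fam_members)
  fam_ids <- sprintf("f%04d", seq_len(n_fam))

  # ancestral CDS and per-copy architecture per family
  fam_arch <- lapply(seq_len(n_fam), function(i) {
    n_cod <- sample(cfg$cds_codons_range[1]:cfg$cds_codons_range[2], 1L)
    n_ex <- sample(cfg$n_exons_range[1]:cfg$n_exons_range[2], 1L)
    list(cds = rand_cds(n_cod), n_exons = n_ex)
  })

  # -- reference layout ------------------------------------------------------
  # Copies of one family go to distinct chromosomes whenever the chromosome
  # count allows: in a real triplicated genome the three subgenome blocks of
  # an ancestral region lie on different chromosomes, which is the premise
  # of the same-chromosome positional-orthology constraint.
  max_glen <- max_gene_length(cfg)
  n_per_sub <- cfg$n_genes_per_subgenome
  cap <- matrix(n_per_sub %/% n_chr, nrow = 3L, ncol = n_chr,
                dimnames = list(labels, chroms))
  if (n_per_sub %% n_chr)
    cap[, seq_len(n_per_sub %% n_chr)] <- cap[, seq_len(n_per_sub %% n_chr)] + 1L
  placement <- vector("list", n_fam)   # per family: chromosome per subgenome
  for (i in sample(seq_len(n_fam))) {
    used <- integer(0)
    chosen <- setNames(integer(0), character(0))
    for (sg in fam_members[[i]]) {
      free <- which(cap[sg, ] > 0L)
      pref <- setdiff(free, used)
      pool <- if (length(pref)) pref else free
      pick <- pool[order(-cap[sg, pool], runif(length(pool)))][1]
      cap[sg, pick] <- cap[sg, pick] - 1L
      used <- c(used, pick)
      chosen[sg] <- pick
    }
    placement[[i]] <- chosen
  }
  # per (subgenome, chromosome) block: family list in random order
  gene_rows <- list()
  gid_counter <- 0L
  for (sg_i in seq_along(labels)) {
    sg <- labels[sg_i]
    for (c_i in seq_len(n_chr)) {
      fams <- which(vapply(placement, function(p)
        sg %in% names(p) && p[[sg]] == c_i, logical(1)))
      if (!length(fams)) next
      fams <- fams[sample.int(length(fams))]
      block_start <- floor((sg_i - 1L) * L / 3) + 1L
      block_end <- floor(sg_i * L / 3)
      W <- (block_end - block_start + 1L) %/% length(fams)
      if (W < max_glen + 300L)
        stop("configuration error: chromosome_length too small for the ",
             "requested gene count")
      for (j in seq_along(fams)) {
        gid_counter <- gid_counter + 1L
        gene_rows[[gid_counter]] <- list(
          gene_id = sprintf("g%05d", gid_counter),
          family = fams[j], chrom = chroms[c_i], subgenome = sg,
          anchor = block_start + (j - 1L) * W + 150L)
      }
    }
  }

  # per-copy CDS: ancestral CDS with paralog drift; copies of one family are
  # forced to distinct proteins so best-hit relations are never tied
  copy_cds <- vapply(gene_rows, function(gr)
    mutate_cds(fam_arch[[gr$family]]$cds, cfg$paralog_divergence),
    character(1))
  fam_idx <- vapply(gene_rows, function(gr) gr$family, integer(1))
  for (fam in unique(fam_idx)) {
    idx <- which(fam_idx == fam)
    repeat {
      prots <- vapply(copy_cds[idx], translate_chr, character(1),
                      USE.NAMES = FALSE)
      d <- which(duplicated(prots))
      if (!length(d)) break
      for (k in d)
        copy_cds[idx[k]] <- mutate_cds_nonsyn(copy_cds[idx[k]], 1L)
    }
  }

  # build gene copies (sequence + relative features)
  built <- vector("list", length(gene_rows))
  for (i in seq_along(gene_rows)) {
    gr <- gene_rows[[i]]
    arch <- fam_arch[[gr$family]]
    cds <- copy_cds[i]
    intron_lens <- sample(cfg$intron_len_range[1]:cfg$intron_len_range[2],
                          max(arch$n_exons - 1L, 0L), replace = TRUE)
    utr5 <- sample(cfg$utr_len_range[1]:cfg$utr_len_range[2], 1L)
    utr3 <- sample(cfg$utr_len_range[1]:cfg$utr_len_range[2], 1L)
    strand <- sample(c("+", "-"), 1L)
    built[[i]] <- build_gene(cds, arch$n_exons, intron_lens, utr5, utr3, strand)
  }

  # assemble chromosomes: random background with genes pasted in
  ref_seq <- setNames(vector("list", n_chr), chroms)
  for (c_i in seq_len(n_chr)) ref_seq[[c_i]] <- strsplit(rand_dna(L), "")[[1]]
  feat_rows <- list()
  gene_meta <- list()
  for (i in seq_along(gene_rows)) {
    gr <- gene_rows[[i]]; bg <- built[[i]]
    s <- gr$anchor; e <- s + bg$length - 1L
    ref_seq[[gr$chrom]][s:e] <- strsplit(bg$seq, "")[[1]]
    f <- bg$feats
    f$start <- f$start + s - 1L; f$end <- f$end + s - 1L
    f$gene_id <- gr$gene_id
    f$chrom <- gr$chrom
    f$ID <- ifelse(f$type == "gene", gr$gene_id,
            ifelse(f$type == "mRNA", paste0(gr$gene_id, ".1"),
                   paste0(gr$gene_id, ".1.", f$type, ".",
                          seq_len(nrow(f)))))
    f$Parent <- ifelse(f$type == "gene", NA_character_,
                ifelse(f$type == "mRNA", gr$gene_id, paste0(gr$gene_id, ".1")))
    feat_rows[[i]] <- f
    gene_meta[[i]] <- data.frame(gene_id = gr$gene_id, family = gr$family,
                                 chrom = gr$chrom, subgenome = gr$subgenome,
                                 start = s, end = e,
                                 strand = f$strand[1],
                                 length = bg$length,
                                 stringsAsFactors = FALSE)
  }
  gene_meta <- do.call(rbind, gene_meta)
  feats_df <- do.call(rbind, feat_rows)
  ref_features <- GenomicRanges::GRanges(
    feats_df$chrom, IRanges::IRanges(feats_df$start, feats_df$end),
    strand = feats_df$strand,
    type = feats_df$type, ID = feats_df$ID, Parent = feats_df$Parent,
    gene_id = feats_df$gene_id, phase = feats_df$phase)
  ref_features <- sort(ref_features, ignore.strand = TRUE)
  ref_seqs <- Biostrings::DNAStringSet(vapply(ref_seq, paste, character(1),
                                              collapse = ""))
  reference <- annotated_genome(ref_seqs, ref_features,
                                setNames(gene_meta$subgenome,
                                         gene_meta$gene_id))

  # -- derive genotypes ------------------------------------------------------
  contig_pad <- 57L + cfg$indel_max_len   # max flank extension + margin
  genotypes <- list(); caller_outputs <- list()
  truth_variants <- list(); events <- list()
  for (gt in cfg$genotype_names) {
    lost <- gene_meta$gene_id[runif(nrow(gene_meta)) < cfg$gene_loss_prob]
    dup_pool <- setdiff(gene_meta$gene_id, lost)
    dup <- dup_pool[runif(length(dup_pool)) < cfg$gene_dup_prob]
    ev <- derive_genotype(reference, gene_meta, lost, dup, cfg, contig_pad)
    genotypes[[gt]] <- ev$genome
    truth_variants[[gt]] <- ev$variants
    caller_outputs[[gt]] <- make_caller_outputs(ev$variants, cfg)
    events[[gt]] <- list(lost = lost, dup = dup, dup_ids = ev$dup_ids)
  }

  # -- outgroups -------------------------------------------------------------
  outgroups <- list()
  for (o_i in seq_along(cfg$outgroup_names)) {
    nm <- cfg$outgroup_names[o_i]
    prots <- vapply(seq_len(n_fam), function(i) {
      aa <- translate_chr(fam_arch[[i]]$cds)
      aa <- sub("\\*$", "", aa)
      mutate_protein(aa, cfg$outgroup_divergence[o_i])
    }, character(1))
    og <- Biostrings::AAStringSet(prots)
    names(og) <- paste0(nm, "_", fam_ids)
    outgroups[[nm]] <- og
  }

  # -- truth tables ----------------------------------------------------------
  truth <- build_truth(cfg, gene_meta, fam_ids, events, truth_variants,
                       genotypes)

  structure(list(reference = reference, genotypes = genotypes,
                 caller_outputs = caller_outputs, outgroups = outgroups,
                 truth = truth, config = cfg),
            class = "pangenome_sim")
}

# place loss/dup/SNP/indel events for one genotype and rebuild its genome
derive_genotype <- function(reference, gene_meta, lost, dup, cfg, contig_pad) {
  chroms <- names(reference$seqs)
  f <- reference$features
  cds_all <- spliced_cds_all(reference)
  variants <- list()
  for (chrom in chroms) {
    refchr <- as.character(reference$seqs[[chrom]])
    L <- nchar(refchr)
    gm <- gene_meta[gene_meta$chrom == chrom, , drop = FALSE]
    # big events first
    big <- list()
    for (g in intersect(lost, gm$gene_id)) {
      row <- gm[gm$gene_id == g, ]
      big[[length(big) + 1L]] <- data.frame(
        chrom = chrom, pos = row$start,
        ref = substr(refchr, row$start, row$end), alt = "",
        type = "gene_loss", gene_id = g, stringsAsFactors = FALSE)
    }
    dup_parent_zone <- list()
    for (g in intersect(dup, gm$gene_id)) {
      row <- gm[gm$gene_id == g, ]
      gseq <- substr(refchr, row$start, row$end)
      dseq <- mutate_gene_copy(gseq, reference, g)
      ins_pos <- row$end + 10L
      big[[length(big) + 1L]] <- data.frame(
        chrom = chrom, pos = ins_pos, ref = "", alt = dseq,
        type = "gene_dup", gene_id = g, stringsAsFactors = FALSE)
      # keep the parent copy variant-free so the duplicate (parent plus 1-3
      # forced amino-acid changes) can never out-score it in RBH
      dup_parent_zone[[length(dup_parent_zone) + 1L]] <- data.frame(
        start = row$start - contig_pad, end = row$end)
    }
    big <- if (length(big)) do.call(rbind, big) else NULL

    # forbidden intervals for small indels: exons (CDS and UTRs) and splice
    # dinucleotides -- coding-region indels are under strong purifying
    # selection, and keeping exons indel-free keeps lifted gene models exact
    sub <- f[GenomeInfoDb::seqnames(f) == chrom]
    ex_f <- sub[sub$type == "exon"]
    forb <- data.frame(start = BiocGenerics::start(ex_f),
                       end = BiocGenerics::end(ex_f))
    for (g in unique(sub$gene_id)) {
      ex <- sub[sub$type == "exon" & sub$gene_id == g]
      if (length(ex) < 2L) next
      es <- sort(BiocGenerics::start(ex)); ee <- sort(BiocGenerics::end(ex))
      int_s <- ee[-length(ee)] + 1L; int_e <- es[-1L] - 1L
      forb <- rbind(forb,
                    data.frame(start = int_s, end = int_s + 1L),
                    data.frame(start = int_e - 1L, end = int_e))
    }

    # exclusion zones around big events (and the dup parents' spans)
    excl <- if (!is.null(big)) {
      span <- pmax(nchar(big$ref), nchar(big$alt))
      data.frame(start = big$pos - contig_pad,
                 end = big$pos + span + contig_pad)
    } else data.frame(start = integer(), end = integer())
    if (length(dup_parent_zone))
      excl <- rbind(excl, do.call(rbind, dup_parent_zone))

    ctx <- build_cds_context(reference, chrom, cds_all)
    n_snp <- rbinom(1L, L, cfg$snp_rate)
    n_ind <- rbinom(1L, L, cfg$indel_rate)
    small <- place_small_variants(refchr, n_snp, n_ind, cfg, excl, forb,
                                  contig_pad, ctx)
    if (nrow(small)) small$chrom <- chrom
    allv <- rbind(big, small)
    if (!is.null(allv) && nrow(allv))
      allv <- allv[order(allv$pos, nchar(allv$ref)), , drop = FALSE]
    variants[[chrom]] <- allv
  }
  vdf <- do.call(rbind, c(variants, list(make.row.names = FALSE)))
  if (is.null(vdf))
    vdf <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), type = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  res <- rebuild_genotype(reference, gene_meta, vdf, lost)
  list(genome = res$genome, variants = vdf, dup_ids = res$dup_ids)
}

# tandem-duplicate a gene with 1-3 guaranteed-nonsynonymous CDS changes so
# the copy clusters with the family but never ties its parent in RBH scoring
mutate_gene_copy <- function(gseq, reference, gene_id) {
  iv <- cds_intervals(reference, gene_id)
  row <- gene_table(reference)
  gstart <- row$start[row$gene_id == gene_id]
  cds <- spliced_cds(reference, gene_id)
  mut <- mutate_cds_nonsyn(cds, sample(1:3, 1L))
  # write mutated CDS back into the gene sequence copy
  chars <- strsplit(gseq, "")[[1]]
  mchars <- strsplit(mut, "")[[1]]
  offset <- 0L
  minus <- iv$strand[1] == "-"
  for (i in seq_len(nrow(iv))) {
    len <- iv$end[i] - iv$start[i] + 1L
    piece <- paste(mchars[(offset + 1L):(offset + len)], collapse = "")
    if (minus) piece <- revcomp_chr(piece)
    rel <- (iv$start[i] - gstart + 1L):(iv$end[i] - gstart + 1L)
    chars[rel] <- strsplit(piece, "")[[1]]
    offset <- offset + len
  }
  paste(chars, collapse = "")
}

place_small_variants <- function(refchr, n_snp, n_ind, cfg, excl, forb,
                                 contig_pad, ctx) {
  L <- nchar(refchr)
  overlaps_any <- function(s, e, tab) {
    if (!nrow(tab)) return(rep(FALSE, length(s)))
    ir_a <- IRanges::IRanges(s, e)
    ir_b <- IRanges::IRanges(tab$start, tab$end)
    IRanges::overlapsAny(ir_a, ir_b)
  }
  acc <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), type = character(),
                    gene_id = character(), stringsAsFactors = FALSE)
  have_snp <- 0L; have_ind <- 0L
  for (iter in seq_len(60L)) {
    need_snp <- n_snp - have_snp; need_ind <- n_ind - have_ind
    if (need_snp <= 0L && need_ind <= 0L) break
    cand_n <- max(2L * (need_snp + need_ind), 10L)
    pos <- sample.int(L - contig_pad - 2L, cand_n, replace = FALSE) + 1L
    is_ind <- c(rep(FALSE, min(need_snp, cand_n)),
                rep(TRUE, max(cand_n - need_snp, 0L)))
    lens <- ifelse(is_ind, sample.int(cfg$indel_max_len, cand_n, replace = TRUE), 1L)
    is_ins <- is_ind & runif(cand_n) < 0.5
    span <- ifelse(is_ind & !is_ins, lens, 1L)
    bad <- overlaps_any(pos - 1L, pos + span - 1L + ifelse(is_ind, 2L, 0L),
                        if (is.null(forb)) excl else rbind(excl, forb))
    bad_snp_only <- overlaps_any(pos, pos + span - 1L, excl)
    drop <- ifelse(is_ind, bad, bad_snp_only)
    cand <- data.frame(pos = pos, is_ind = is_ind, len = lens,
                       is_ins = is_ins, span = span)[!drop, , drop = FALSE]
    # greedy separation against accepted + earlier candidates
    prev_pos <- acc$pos
    prev_reach <- if (nrow(acc)) acc$pos + pmax(nchar(acc$ref), 1L) + contig_pad
                  else integer(0)
    cand <- cand[order(cand$pos), , drop = FALSE]
    keep <- logical(nrow(cand))
    allpos <- c(prev_pos, rep(NA_integer_, nrow(cand)))
    allreach <- c(prev_reach, rep(NA_integer_, nrow(cand)))
    np <- length(prev_pos)
    for (i in seq_len(nrow(cand))) {
      p <- cand$pos[i]; reach <- p + cand$span[i] + contig_pad
      lo <- p - contig_pad - cfg$indel_max_len - 2L
      clash <- any(!is.na(allpos) & allpos <= p + cand$span[i] + contig_pad &
                   allreach >= p, na.rm = TRUE)
      if (!clash) {
        keep[i] <- TRUE
        np <- np + 1L
        allpos[np] <- p; allreach[np] <- reach
      }
    }
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    take_snp <- utils::head(which(!cand$is_ind), need_snp)
    take_ind <- utils::head(which(cand$is_ind), need_ind)
    cand <- cand[sort(c(take_snp, take_ind)), , drop = FALSE]
    if (!nrow(cand)) next
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      p <- cand$pos[i]
      if (!cand$is_ind[i]) {
        alt <- choose_snp_alt(ctx, refchr, p)
        if (is.na(alt)) return(NULL)       # protected codon position
        data.frame(chrom = NA_character_, pos = p,
                   ref = substr(refchr, p, p), alt = alt, type = "snp",
                   gene_id = NA_character_, stringsAsFactors = FALSE)
      } else if (cand$is_ins[i]) {
        data.frame(chrom = NA_character_, pos = p, ref = "",
                   alt = rand_dna(cand$len[i]), type = "ins",
                   gene_id = NA_character_, stringsAsFactors = FALSE)
      } else {
        data.frame(chrom = NA_character_, pos = p,
                   ref = substr(refchr, p, p + cand$len[i] - 1L), alt = "",
                   type = "del", gene_id = NA_character_,
                   stringsAsFactors = FALSE)
      }
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) next
    add <- do.call(rbind, rows)
    have_snp <- have_snp + sum(add$type == "snp")
    have_ind <- have_ind + sum(add$type %in% c("ins", "del"))
    acc <- rbind(acc, add)
  }
  acc <- acc[order(acc$pos), , drop = FALSE]
  acc
}

# rebuild one genotype: sequence, lifted gene models, inserted duplicates
rebuild_genotype <- function(reference, gene_meta, vdf, lost) {
  chroms <- names(reference$seqs)
  out_seq <- setNames(character(length(chroms)), chroms)
  f <- reference$features
  keep <- !(f$gene_id %in% lost)
  dup_ids <- character(0)
  new_feat_rows <- list()
  for (chrom in chroms) {
    refchr <- as.character(reference$seqs[[chrom]])
    L <- nchar(refchr)
    x <- vdf[!is.na(vdf$chrom) & vdf$chrom == chrom, , drop = FALSE]
    x <- x[order(x$pos), , drop = FALSE]
    n <- nrow(x)
    # sequence by splicing (independent of apply_variants)
    if (n) {
      pieces <- character(0)
      cursor <- 1L
      for (i in seq_len(n)) {
        if (x$pos[i] > cursor)
          pieces <- c(pieces, substr(refchr, cursor, x$pos[i] - 1L))
        pieces <- c(pieces, x$alt[i])
        cursor <- x$pos[i] + nchar(x$ref[i])
      }
      if (cursor <= L) pieces <- c(pieces, substr(refchr, cursor, L))
      out_seq[[chrom]] <- paste(pieces, collapse = "")
    } else out_seq[[chrom]] <- refchr
    # offset function: delta applied to positions after each indel
    delta <- nchar(x$alt) - nchar(x$ref)
    ind <- which(delta != 0L)
    shift_of <- function(p) {
      if (!length(ind)) return(rep(0L, length(p)))
      del_end <- x$pos[ind] + pmax(nchar(x$ref[ind]), 1L) - 1L
      ins <- nchar(x$ref[ind]) == 0L
      vapply(p, function(pp)
        sum(delta[ind][(ins & x$pos[ind] <= pp) | (!ins & del_end < pp)]),
        integer(1))
    }
    # lift surviving features on this chromosome
    sub_idx <- which(keep & as.character(GenomeInfoDb::seqnames(f)) == chrom)
    if (length(sub_idx)) {
      sub <- f[sub_idx]
      ns <- BiocGenerics::start(sub) + shift_of(BiocGenerics::start(sub))
      ne <- BiocGenerics::end(sub) + shift_of(BiocGenerics::end(sub) + 0L)
      new_feat_rows[[length(new_feat_rows) + 1L]] <- data.frame(
        chrom = chrom, start = ns, end = ne,
        strand = as.character(BiocGenerics::strand(sub)),
        type = sub$type, ID = sub$ID, Parent = sub$Parent,
        gene_id = sub$gene_id, phase = sub$phase, stringsAsFactors = FALSE)
    }
    # duplicate gene features at their insertion sites
    dups <- x[x$type == "gene_dup", , drop = FALSE]
    for (i in seq_len(nrow(dups))) {
      parent <- dups$gene_id[i]
      plen <- nchar(dups$alt[i])
      gstart <- dups$pos[i] + shift_of(dups$pos[i]) - plen
      pf <- f[f$gene_id == parent]
      prow <- gene_meta[gene_meta$gene_id == parent, ]
      rel_s <- BiocGenerics::start(pf) - prow$start
      rel_e <- BiocGenerics::end(pf) - prow$start
      did <- paste0(parent, "_dup")
      dup_ids <- c(dup_ids, did)
      new_feat_rows[[length(new_feat_rows) + 1L]] <- data.frame(
        chrom = chrom, start = gstart + rel_s, end = gstart + rel_e,
        strand = as.character(BiocGenerics::strand(pf)),
        type = pf$type,
        ID = sub(parent, did, pf$ID, fixed = TRUE),
        Parent = ifelse(pf$type == "gene", NA_character_,
                 ifelse(pf$type == "mRNA", did,
                        paste0(did, ".1"))),
        gene_id = did, phase = pf$phase, stringsAsFactors = FALSE)
    }
  }
  nf <- do.call(rbind, c(new_feat_rows, list(make.row.names = FALSE)))
  gr <- GenomicRanges::GRanges(nf$chrom, IRanges::IRanges(nf$start, nf$end),
                               strand = nf$strand, type = nf$type, ID = nf$ID,
                               Parent = nf$Parent, gene_id = nf$gene_id,
                               phase = nf$phase)
  gr <- sort(gr, ignore.strand = TRUE)
  sg <- reference$subgenome
  extra <- setNames(unname(sg[sub("_dup$", "", dup_ids)]), dup_ids)
  genome <- annotated_genome(Biostrings::DNAStringSet(out_seq), gr,
                             c(sg[setdiff(names(sg), lost)], extra))
  list(genome = genome, dup_ids = dup_ids)
}

make_caller_outputs <- function(vdf, cfg) {
  callers <- c("bubble", "path_divergence")
  rows <- list()
  for (i in seq_len(nrow(vdf))) {
    span <- max(nchar(vdf$ref[i]), nchar(vdf$alt[i]), 1L)
    reported <- callers
    if (runif(1L) < cfg$caller_miss_prob)
      reported <- sample(callers, 1L)
    bub_len <- span + sample(10:30, 1L)
    pd_len <- if (runif(1L) < cfg$longer_contig_frac)
      bub_len + sample(5:25, 1L) else span + sample(10:30, 1L)
    for (cl in reported) {
      q <- if (runif(1L) < cfg$low_quality_prob) sample(0:29, 1L)
           else sample(30:60, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = vdf$chrom[i], pos = vdf$pos[i], ref = vdf$ref[i],
        alt = vdf$alt[i],
        contig_length = if (cl == "bubble") bub_len else pd_len,
        flank_quality = q, caller = cl, stringsAsFactors = FALSE)
    }
  }
  all <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), contig_length = integer(),
               flank_quality = integer(), caller = character(),
               stringsAsFactors = FALSE)
  out <- lapply(callers, function(cl) {
    df <- all[all$caller == cl, , drop = FALSE]
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("variant_calls", "data.frame")
    df
  })
  setNames(out, callers)
}

build_truth <- function(cfg, gene_meta, fam_ids, events, truth_variants,
                        genotypes) {
  gts <- cfg$genotype_names
  refn <- cfg$reference_name
  lost1 <- events[[gts[1]]]$lost; lost2 <- events[[gts[2]]]$lost
  # pan classes
  pan <- list()
  for (g in gene_meta$gene_id) {
    in1 <- !(g %in% lost1); in2 <- !(g %in% lost2)
    cls_ref <- if (in1 && in2) "common" else if (in1 || in2) "dispensable" else "unique"
    pan[[length(pan) + 1L]] <- data.frame(genome = refn, gene_id = g,
                                          class = cls_ref)
    if (in1) pan[[length(pan) + 1L]] <- data.frame(
      genome = gts[1], gene_id = g,
      class = if (in2) "common" else "dispensable")
    if (in2) pan[[length(pan) + 1L]] <- data.frame(
      genome = gts[2], gene_id = g,
      class = if (in1) "common" else "dispensable")
  }
  for (gt in gts)
    for (d in events[[gt]]$dup_ids)
      pan[[length(pan) + 1L]] <- data.frame(genome = gt, gene_id = d,
                                            class = "unique")
  pan <- do.call(rbind, pan)

  # ortholog map: family -> copies per genome
  omap <- list()
  for (i in seq_len(nrow(gene_meta))) {
    g <- gene_meta$gene_id[i]; famid <- fam_ids[gene_meta$family[i]]
    omap[[length(omap) + 1L]] <- data.frame(family = famid, genome = refn,
                                            gene_id = g)
    for (gt in gts)
      if (!(g %in% events[[gt]]$lost))
        omap[[length(omap) + 1L]] <- data.frame(family = famid, genome = gt,
                                                gene_id = g)
  }
  for (gt in gts)
    for (d in events[[gt]]$dup_ids) {
      parent <- sub("_dup$", "", d)
      famid <- fam_ids[gene_meta$family[gene_meta$gene_id == parent]]
      omap[[length(omap) + 1L]] <- data.frame(family = famid, genome = gt,
                                              gene_id = d)
    }
  omap <- do.call(rbind, omap)

  # copy counts per outgroup gene x genome
  cc <- list()
  fam_of_gene <- setNames(fam_ids[gene_meta$family], gene_meta$gene_id)
  for (og in cfg$outgroup_names)
    for (fi in seq_along(fam_ids)) {
      famid <- fam_ids[fi]
      base <- sum(fam_of_gene == famid)
      for (gn in c(refn, gts)) {
        n <- base
        if (gn != refn) {
          n <- n - sum(fam_of_gene[events[[gn]]$lost] == famid, na.rm = TRUE)
          dup_parents <- sub("_dup$", "", events[[gn]]$dup_ids)
          n <- n + sum(fam_of_gene[dup_parents] == famid, na.rm = TRUE)
        }
        cc[[length(cc) + 1L]] <- data.frame(
          outgroup = og, outgroup_gene = paste0(og, "_", famid),
          family = famid, genome = gn, count = n)
      }
    }
  cc <- do.call(rbind, cc)

  # subgenome truth
  sgt <- list(data.frame(genome = refn, gene_id = gene_meta$gene_id,
                         label = gene_meta$subgenome))
  for (gt in gts) {
    sg <- genotypes[[gt]]$subgenome
    sgt[[length(sgt) + 1L]] <- data.frame(genome = gt, gene_id = names(sg),
                                          label = unname(sg))
  }
  sgt <- do.call(rbind, sgt)

  list(variants = truth_variants, pan_class = pan, ortholog_map = omap,
       copy_counts = cc, subgenome = sgt)
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat("pangenome_sim:\n  reference: ")
  print(x$reference)
  cat(sprintf("  genotypes: %s\n", paste(names(x$genotypes), collapse = ", ")))
  nv <- vapply(x$truth$variants, nrow, integer(1))
  cat(sprintf("  true variants: %s\n",
              paste(names(nv), nv, sep = "=", collapse = " ")))
  invisible(x)
}

# ---- writing simulated inputs ---------------------------------------------

#' Write all simulated pipeline inputs to a directory
#'
#' Emits the reference genome (FASTA + GFF3 + subgenome TSV), one VCF per
#' genotype and caller (INFO keys `CONTIGLEN`, `FLANKQ`, `CALLER`), the
#' outgroup proteomes (FASTA), and the truth tables (TSV; genotype genomes as
#' FASTA/GFF3 under `truth/`).
#'
#' @param sim A `pangenome_sim` from [simulate_pangenome()].
#' @param out_dir Output directory (created if needed).
#' @return A manifest data.frame (`file`, `records`), invisibly-printable.
#' @export
write_inputs <- function(sim, out_dir) {
  stopifnot(inherits(sim, "pangenome_sim"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("I/O error: cannot write to directory ", out_dir)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  manifest <- list()
  note <- function(file, records)
    manifest[[length(manifest) + 1L]] <<- data.frame(file = file,
                                                     records = records)
  ref <- sim$reference
  write_genome_fasta(ref$seqs, file.path(out_dir, "reference.fasta"))
  note("reference.fasta", length(ref$seqs))
  write_gff3(ref$features, file.path(out_dir, "reference.gff3"),
             setNames(as.integer(lengths(ref$seqs)), names(ref$seqs)))
  note("reference.gff3", length(ref$features))
  sg <- gene_table(ref)[, c("gene_id", "chrom", "start", "end", "subgenome")]
  names(sg)[5] <- "label"
  write_tsv(sg, file.path(out_dir, "reference_subgenomes.tsv"))
  note("reference_subgenomes.tsv", nrow(sg))
  for (gt in names(sim$caller_outputs)) {
    for (cl in names(sim$caller_outputs[[gt]])) {
      fn <- sprintf("calls_%s_%s.vcf", gt, cl)
      calls <- sim$caller_outputs[[gt]][[cl]]
      write_vcf(calls, ref$seqs, file.path(out_dir, fn))
      note(fn, nrow(calls))
    }
  }
  for (og in names(sim$outgroups)) {
    fn <- sprintf("outgroup_%s.faa", og)
    write_proteome_fasta(sim$outgroups[[og]], file.path(out_dir, fn))
    note(fn, length(sim$outgroups[[og]]))
  }
  for (gt in names(sim$genotypes)) {
    g <- sim$genotypes[[gt]]
    fa <- sprintf("truth/%s.fasta", gt); gf <- sprintf("truth/%s.gff3", gt)
    write_genome_fasta(g$seqs, file.path(out_dir, fa))
    note(fa, length(g$seqs))
    write_gff3(g$features, file.path(out_dir, gf),
               setNames(as.integer(lengths(g$seqs)), names(g$seqs)))
    note(gf, length(g$features))
    tv <- sprintf("truth/variants_%s.tsv", gt)
    write_tsv(sim$truth$variants[[gt]], file.path(out_dir, tv))
    note(tv, nrow(sim$truth$variants[[gt]]))
  }
  for (nm in c("pan_class", "ortholog_map", "copy_counts", "subgenome")) {
    fn <- sprintf("truth/%s.tsv", nm)
    write_tsv(sim$truth[[nm]], file.path(out_dir, fn))
    note(fn, nrow(sim$truth[[nm]]))
  }
  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  out
}
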