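#' Pipeline configuration
#'
#' Collects the file paths and parameters needed by [run_pipeline()]. Two
#' genotypes are compared against the reference; each genotype supplies one
#' VCF per caller. A genotype annotation GFF3 (e.g. from a re-annotation of
#' the reconstructed genome) is optional -- without one, the reference gene
#' models are lifted through the coordinate map instead, so genes gained by
#' the genotype cannot be discovered.
#'
#' @param reference_fasta,reference_gff3 Reference genome and gene models.
#' @param subgenome_tsv Published per-gene subgenome labels
#'   (`gene_id`, `chrom`, `start`, `end`, `label`).
#' @param genotype_vcfs Named list (one element per genotype) of character
#'   vectors of caller VCF paths.
#' @param genotype_gff3 Optional named list of genotype annotation GFF3s.
#' @param outgroup_fastas Named character vector of outgroup proteome FASTAs.
#' @param out_dir Output directory.
#' @param q_min Minimum 5'-flank mapping quality (default 30).
#' @param overlap_thresholds Annotation-overlap fractions for reports.
#' @param inclusion_ratio,score_floor Orthology parameters.
#' @param seed Integer seed recorded in the manifest.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_fasta, reference_gff3, subgenome_tsv,
                            genotype_vcfs, genotype_gff3 = NULL,
                            outgroup_fastas = character(),
                            out_dir = "pangenome_out", q_min = 30,
                            overlap_thresholds = c(1, 0.75, 0.5, 0.25),
                            inclusion_ratio = 0.8, score_floor = 50,
                            seed = 1L) {
  cfg <- list(reference_fasta = reference_fasta,
              reference_gff3 = reference_gff3,
              subgenome_tsv = subgenome_tsv,
              genotype_vcfs = genotype_vcfs,
              genotype_gff3 = genotype_gff3,
              outgroup_fastas = outgroup_fastas,
              out_dir = out_dir, q_min = q_min,
              overlap_thresholds = overlap_thresholds,
              inclusion_ratio = inclusion_ratio, score_floor = score_floor,
              seed = as.integer(seed))
  inputs <- c(reference_fasta, reference_gff3, subgenome_tsv,
              unlist(genotype_vcfs), unlist(genotype_gff3),
              unlist(outgroup_fastas))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (is.null(names(genotype_vcfs)) || length(genotype_vcfs) != 2L)
    stop("genotype_vcfs must be a named list with two genotypes")
  if (!(inclusion_ratio > 0 && inclusion_ratio <= 1))
    stop("inclusion_ratio must lie in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @param overrides Named list of values taking precedence over the file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  do.call(pipeline_config, y)
}

#' Run the full pan-genome pipeline
#'
#' Executes merge, filter, apply, effect annotation, region classification,
#' positional orthology, pan-genome classification with retained/lost
#' calling, and subgenome transfer with summaries. Every artifact is written
#' under `out_dir` and listed in the returned manifest with a record count
#' and an md5 checksum; per-stage input/output counts are logged via
#' `message()`.
#'
#' @param config A [pipeline_config()].
#' @return The manifest data.frame (`stage`, `file`, `records`, `md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(stage, file, records) {
    path <- file.path(out_dir, file)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = file, records = records,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    message(sprintf("[%s] start", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ref_seqs <- read_genome_fasta(config$reference_fasta)
  ref_feats <- read_gff3(config$reference_gff3)
  pub <- read_tsv(config$subgenome_tsv)
  reference <- annotated_genome(ref_seqs, ref_feats,
                                setNames(pub$label, pub$gene_id))
  gts <- names(config$genotype_vcfs)

  merged <- list(); filtered <- list(); rebuilt <- list()
  genomes <- list(reference = reference)
  names(genomes) <- "reference"

  for (gt in gts) {
    # 1. merge the two callers' outputs
    stage("merge", {
      vcfs <- lapply(config$genotype_vcfs[[gt]], read_vcf)
      m <- Reduce(merge_caller_outputs, vcfs)
      merged[[gt]] <- m
      write_vcf(m, ref_seqs, file.path(out_dir, sprintf("%s_merged.vcf", gt)))
      emit("merge", sprintf("%s_merged.vcf", gt), nrow(m))
      message(sprintf("[merge] %s: %s calls in -> %d merged", gt,
                      paste(vapply(vcfs, nrow, integer(1)), collapse = "+"),
                      nrow(m)))
    })
    # 2. quality filter
    stage("filter", {
      fl <- filter_variants(merged[[gt]], q_min = config$q_min)
      filtered[[gt]] <- fl
      write_vcf(fl, ref_seqs, file.path(out_dir, sprintf("%s_filtered.vcf", gt)))
      emit("filter", sprintf("%s_filtered.vcf", gt), nrow(fl))
      message(sprintf("[filter] %s: %d -> %d calls (q_min=%s)", gt,
                      nrow(merged[[gt]]), nrow(fl), format(config$q_min)))
    })
    # 3. reconstruct the pseudo-genome
    stage("apply", {
      res <- apply_variants(reference, filtered[[gt]])
      rebuilt[[gt]] <- res
      write_genome_fasta(res$seqs, file.path(out_dir, sprintf("%s.fasta", gt)))
      emit("apply", sprintf("%s.fasta", gt), length(res$seqs))
      write_chain(res$map, file.path(out_dir, sprintf("%s.chain", gt)))
      emit("apply", sprintf("%s.chain", gt), nrow(res$map$blocks))
      message(sprintf("[apply] %s: genome %d bp (reference %d bp)", gt,
                      sum(lengths(res$seqs)), sum(lengths(ref_seqs))))
    })
  }

  # 4. coding-effect annotation (variants vs reference models)
  effects_all <- list()
  stage("effects", {
    for (gt in gts) {
      ef <- annotate_effects(filtered[[gt]], reference)
      ef$genotype <- rep(gt, nrow(ef))
      effects_all[[gt]] <- ef
    }
    eff <- do.call(rbind, effects_all)
    write_tsv(eff, file.path(out_dir, "effects.tsv"))
    emit("effects", "effects.tsv", nrow(eff))
    aff <- count_affected_genes(eff)
    write_tsv(aff, file.path(out_dir, "affected_genes.tsv"))
    emit("effects", "affected_genes.tsv", nrow(aff))
    message(sprintf("[effects] affected genes: %s",
                    paste(aff$genotype, aff$affected_genes, sep = "=",
                          collapse = " ")))
  })

  # 5. region classification over subgenomes
  stage("classify-regions", {
    for (gt in gts) {
      rc <- classify_regions(filtered[[gt]], reference)
      write_tsv(as.data.frame(rc), file.path(out_dir,
                sprintf("%s_region_counts.tsv", gt)))
      emit("classify-regions", sprintf("%s_region_counts.tsv", gt), nrow(rc))
    }
  })

  # genotype gene models: supplied annotation, or reference models lifted
  # through the coordinate map (genes fully deleted in the genotype drop out)
  for (gt in gts) {
    genomes[[gt]] <- if (!is.null(config$genotype_gff3[[gt]]))
      annotated_genome(rebuilt[[gt]]$seqs, read_gff3(config$genotype_gff3[[gt]]))
    else lift_annotation(reference, rebuilt[[gt]]$map, rebuilt[[gt]]$seqs)
  }

  # 6. positional orthology
  proteomes <- lapply(genomes, extract_proteins)
  ortho <- list()
  stage("orthologs", {
    pairs <- list(c("reference", gts[1]), c("reference", gts[2]), gts)
    for (p in pairs) {
      key <- paste(p, collapse = "~")
      po <- positional_orthologs(genomes[[p[1]]], genomes[[p[2]]],
                                 score_floor = config$score_floor,
                                 proteome_a = proteomes[[p[1]]],
                                 proteome_b = proteomes[[p[2]]])
      ortho[[key]] <- po
      fn <- sprintf("orthologs_%s_%s.tsv", p[1], p[2])
      write_tsv(po, file.path(out_dir, fn))
      emit("orthologs", fn, nrow(po))
      message(sprintf("[orthologs] %s: %d positional pairs", key, nrow(po)))
    }
  })

  # 7. pan-genome classification, copy counts, retained/lost
  classes <- NULL; statuses <- NULL; cc_all <- NULL
  stage("pangenome", {
    classes <- classify_pangenes(
      ortho[[1]], ortho[[2]], ortho[[3]],
      genomes[["reference"]], genomes[[gts[1]]], genomes[[gts[2]]],
      genome_names = c("reference", gts))
    write_tsv(classes, file.path(out_dir, "pan_classes.tsv"))
    emit("pangenome", "pan_classes.tsv", nrow(classes))
    if (length(config$outgroup_fastas)) {
      ccs <- list()
      for (og in names(config$outgroup_fastas)) {
        ogp <- read_proteome_fasta(config$outgroup_fastas[[og]])
        for (gn in names(genomes)) {
          cc <- ortholog_copy_counts(ogp, proteomes[[gn]],
                                     inclusion_ratio = config$inclusion_ratio,
                                     score_floor = config$score_floor)
          cc$genome <- gn; cc$outgroup <- og
          ccs[[length(ccs) + 1L]] <- cc
        }
      }
      cc_all <- do.call(rbind, ccs)
      write_tsv(cc_all, file.path(out_dir, "copy_counts.tsv"))
      emit("pangenome", "copy_counts.tsv", nrow(cc_all))
      st <- list()
      for (og in unique(cc_all$outgroup))
        st[[og]] <- call_retained_lost(cc_all[cc_all$outgroup == og, ])
      statuses <- do.call(rbind, c(st, list(make.row.names = FALSE)))
      write_tsv(statuses, file.path(out_dir, "retained_lost.tsv"))
      emit("pangenome", "retained_lost.tsv", nrow(statuses))
    }
  })

  # 8. subgenome transfer + summaries
  stage("subgenomes", {
    sg_rows <- list(data.frame(genome = "reference",
                               gene_id = pub$gene_id, label = pub$label,
                               stringsAsFactors = FALSE))
    for (gt in gts) {
      key <- paste("reference", gt, sep = "~")
      rbh <- ortho[[key]]
      # transfer works genotype -> reference, so swap pair orientation
      pairs <- data.frame(gene_a = rbh$gene_b, gene_b = rbh$gene_a)
      tr <- transfer_assignments(genomes[[gt]], pub[, c("gene_id", "label")],
                                 pairs)
      fn <- sprintf("%s_subgenomes.tsv", gt)
      write_tsv(tr, file.path(out_dir, fn))
      emit("subgenomes", fn, nrow(tr))
      sg_rows[[length(sg_rows) + 1L]] <- data.frame(
        genome = gt, gene_id = tr$gene_id, label = tr$label,
        stringsAsFactors = FALSE)
    }
    summ <- summarize_pangenome(classes, statuses, cc_all,
                                do.call(rbind, sg_rows))
    write_tsv(summ$class_counts, file.path(out_dir, "summary_classes.tsv"))
    emit("subgenomes", "summary_classes.tsv", nrow(summ$class_counts))
    if (!is.null(summ$subgenome_changes)) {
      write_tsv(summ$subgenome_changes,
                file.path(out_dir, "summary_subgenomes.tsv"))
      emit("subgenomes", "summary_subgenomes.tsv",
           nrow(summ$subgenome_changes))
    }
  })

  out <- do.call(rbind, manifest)
  write_tsv(out, file.path(out_dir, "manifest.tsv"))
  out
}

#' Lift a reference annotation through a coordinate map
#'
#' Projects the reference gene models onto a reconstructed genotype genome.
#' Features any of whose endpoints fall in deleted regions -- and all
#' features of their gene -- are dropped.
#'
#' @param reference An `annotated_genome`.
#' @param map A `coordinate_map` from [apply_variants()].
#' @param target_seqs The reconstructed `DNAStringSet`.
#' @return An `annotated_genome` on genotype coordinates.
#' @export
lift_annotation <- function(reference, map, target_seqs) {
  f <- reference$features
  chrom <- as.character(GenomeInfoDb::seqnames(f))
  ns <- lift_positions(map, chrom, BiocGenerics::start(f))
  ne <- lift_positions(map, chrom, BiocGenerics::end(f))
  bad_genes <- unique(f$gene_id[is.na(ns) | is.na(ne)])
  keep <- !(f$gene_id %in% bad_genes)
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(ns[keep], ne[keep]),
                               strand = BiocGenerics::strand(f)[keep],
                               type = f$type[keep], ID = f$ID[keep],
                               Parent = f$Parent[keep],
                               gene_id = f$gene_id[keep],
                               phase = f$phase[keep])
  annotated_genome(target_seqs, gr,
                   reference$subgenome[setdiff(names(reference$subgenome),
                                               bad_genes)])
}
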