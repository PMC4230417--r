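#' Assign subgenome labels by coordinate overlap
#'
#' A new gene model inherits the published subgenome label of a reference
#' gene when both lie on the same chromosome and overlap reciprocally by at
#' least `min_overlap` of each feature's length. When several published
#' genes qualify, the one with the largest reciprocal overlap wins (then the
#' leftmost). Unmatched genes stay `unassigned`.
#'
#' @param new_models `GRanges` of gene features (with `gene_id`) or an
#'   `annotated_genome`.
#' @param published Data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `label`.
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return A data.frame with `gene_id`, `label`, `provenance`
#'   (`coordinate` or `none`).
#' @export
assign_by_coordinates <- function(new_models, published, min_overlap = 0.5) {
  new <- as_feature_ranges(new_models)
  pub <- GenomicRanges::GRanges(published$chrom,
                                IRanges::IRanges(published$start,
                                                 published$end))
  ov <- GenomicRanges::findOverlaps(new, pub, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  inter <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(new)[q], IRanges::ranges(pub)[s]))
  frac_new <- inter / BiocGenerics::width(new)[q]
  frac_pub <- inter / BiocGenerics::width(pub)[s]
  ok <- frac_new >= min_overlap & frac_pub >= min_overlap
  q <- q[ok]; s <- s[ok]
  recip <- pmin(frac_new, frac_pub)[ok]
  label <- rep("unassigned", length(new))
  if (length(q)) {
    o <- order(q, -recip, published$start[s])
    first <- o[!duplicated(q[o])]
    label[q[first]] <- published$label[s[first]]
  }
  data.frame(gene_id = new$gene_id, label = label,
             provenance = ifelse(label == "unassigned", "none", "coordinate"),
             stringsAsFactors = FALSE)
}

#' Transfer subgenome assignments to a genotype's genes
#'
#' Priority 1: a gene takes the label of its reciprocal best hit in the
#' reference, when that hit is labeled. Priority 2: the nearest labeled
#' flanking genes (one upstream, one downstream in chromosome order, skipping
#' unlabeled neighbours) agree -- the gene takes their shared label.
#' Otherwise the gene stays `unassigned`. Chromosome-terminal genes with a
#' single labeled neighbour cannot satisfy the flank rule.
#'
#' @param genotype_genome An `annotated_genome` (supplies gene order), or a
#'   data.frame with `gene_id`, `chrom`, `start`.
#' @param reference_assignments Data.frame with `gene_id`, `label` for the
#'   reference genes.
#' @param rbh_pairs Data.frame with `gene_a` (genotype gene) and `gene_b`
#'   (reference gene), e.g. from [positional_orthologs()].
#' @return A data.frame with `gene_id`, `chrom`, `start`, `label`,
#'   `provenance` (`rbh_transfer`, `flank_transfer` or `none`).
#' @export
transfer_assignments <- function(genotype_genome, reference_assignments,
                                 rbh_pairs) {
  gt <- if (inherits(genotype_genome, "annotated_genome"))
    gene_table(genotype_genome)
  else as.data.frame(genotype_genome)
  stopifnot(all(c("gene_id", "chrom", "start") %in% names(gt)))
  gt <- gt[order(gt$chrom, gt$start), , drop = FALSE]
  ref_lab <- setNames(reference_assignments$label,
                      reference_assignments$gene_id)
  label <- rep("unassigned", nrow(gt))
  prov <- rep("none", nrow(gt))
  # priority 1: RBH transfer
  partner <- rbh_pairs$gene_b[match(gt$gene_id, rbh_pairs$gene_a)]
  got <- unname(ref_lab[partner])
  ok <- !is.na(got) & got != "unassigned"
  label[ok] <- got[ok]
  prov[ok] <- "rbh_transfer"
  # priority 2: agreeing labeled flanks (labels from round 1 only)
  for (ch in unique(gt$chrom)) {
    idx <- which(gt$chrom == ch)
    lab <- label[idx]
    labeled <- which(lab != "unassigned")
    for (j in which(lab == "unassigned")) {
      up <- labeled[labeled < j]
      down <- labeled[labeled > j]
      if (!length(up) || !length(down)) next
      l1 <- lab[max(up)]; l2 <- lab[min(down)]
      if (l1 == l2) {
        label[idx[j]] <- l1
        prov[idx[j]] <- "flank_transfer"
      }
    }
  }
  data.frame(gene_id = gt$gene_id, chrom = gt$chrom, start = gt$start,
             label = label, provenance = prov, stringsAsFactors = FALSE)
}
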