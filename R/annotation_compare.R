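#' Compare two gene-model sets at one minimum-overlap threshold
#'
#' A reference feature matches a new feature when their intersection covers
#' at least `f` of the reference feature's length (the fraction is
#' denominated on the reference feature only) and both lie on the same
#' strand. Reference features matching exactly one new feature that itself
#' matches no other reference feature are `overlap_reciprocal`; a reference
#' feature matching two or more new features is `overlap_split`; reference
#' features sharing their single new partner with other reference features
#' are `overlap_join`. Unmatched features are `only_ref` / `only_new`.
#'
#' @param ref_models,new_models `GRanges` of features (or `annotated_genome`
#'   objects, compared at gene level).
#' @param f Minimum overlap fraction, in (0, 1].
#' @return A one-row data.frame with the six category counts
#'   (`overlap_total = reciprocal + split + join`, counted in reference
#'   features).
#' @export
compare_annotations <- function(ref_models, new_models, f) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("parameter error: f must lie in (0, 1]")
  ref <- as_feature_ranges(ref_models)
  new <- as_feature_ranges(new_models)
  ed <- overlap_edges(ref, new, f)
  ref_deg <- tabulate(ed$ref, nbins = length(ref))
  new_deg <- tabulate(ed$new, nbins = length(new))
  partner_deg <- rep(0L, length(ref))
  single <- which(ref_deg == 1L)
  if (length(single)) {
    partner <- ed$new[match(single, ed$ref)]
    partner_deg[single] <- new_deg[partner]
  }
  reciprocal <- sum(ref_deg == 1L & partner_deg == 1L)
  split <- sum(ref_deg >= 2L)
  join <- sum(ref_deg == 1L & partner_deg >= 2L)
  data.frame(f = f,
             only_ref = sum(ref_deg == 0L),
             only_new = sum(new_deg == 0L),
             overlap_reciprocal = reciprocal,
             overlap_split = split,
             overlap_join = join,
             overlap_total = reciprocal + split + join)
}

as_feature_ranges <- function(x) {
  if (inherits(x, "annotated_genome")) gene_ranges(x)
  else if (is(x, "GRanges")) x
  else stop("expected a GRanges or annotated_genome")
}

# edge list (ref index, new index) under the reference-denominated overlap
# fraction; strands must agree
overlap_edges <- function(ref, new, f) {
  ov <- GenomicRanges::findOverlaps(ref, new, ignore.strand = FALSE)
  if (!length(ov)) return(data.frame(ref = integer(), new = integer()))
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  inter <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(ref)[q], IRanges::ranges(new)[s]))
  need <- f * BiocGenerics::width(ref)[q]
  keep <- inter >= need - 1e-9
  data.frame(ref = q[keep], new = s[keep])
}

#' Compare annotations at several thresholds and levels
#'
#' Gene-level rows compare transcript spans; exon-level rows compare
#' individual exon intervals.
#'
#' @param ref_genome,new_genome `annotated_genome` objects.
#' @param thresholds Minimum-overlap fractions (default `1, 0.75, 0.5, 0.25`).
#' @return A data.frame with one row per threshold and level.
#' @export
compare_annotation_table <- function(ref_genome, new_genome,
                                     thresholds = c(1, 0.75, 0.5, 0.25)) {
  rows <- list()
  for (f in thresholds) {
    g <- compare_annotations(gene_ranges(ref_genome), gene_ranges(new_genome), f)
    g$level <- "gene"
    e <- compare_annotations(exon_ranges(ref_genome), exon_ranges(new_genome), f)
    e$level <- "exon"
    rows <- c(rows, list(g, e))
  }
  out <- do.call(rbind, rows)
  out[, c("f", "level", setdiff(names(out), c("f", "level")))]
}

#' Fraction of reference features recovered by a new annotation
#'
#' The recovered fraction at threshold `f` is the share of reference
#' features participating in any overlap category; it is non-decreasing as
#' `f` decreases.
#'
#' @param ref_models,new_models Feature sets as in [compare_annotations()].
#' @param thresholds Overlap fractions, sorted descending.
#' @return A data.frame with `f` and `recovered`.
#' @export
coverage_curve <- function(ref_models, new_models,
                           thresholds = c(1, 0.75, 0.5, 0.25)) {
  ref <- as_feature_ranges(ref_models)
  n_ref <- length(ref)
  rec <- vapply(thresholds, function(f) {
    row <- compare_annotations(ref_models, new_models, f)
    if (n_ref == 0L) return(0)
    (n_ref - row$only_ref) / n_ref
  }, numeric(1))
  data.frame(f = thresholds, recovered = rec)
}
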