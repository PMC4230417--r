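#' Construct a variant-call table
#'
#' One row per caller-reported difference versus the reference. Alleles use
#' an un-anchored convention: a SNP/MNV has equal-length `ref`/`alt`; a
#' deletion has `alt == ""` and removes `pos..pos+nchar(ref)-1`; an insertion
#' has `ref == ""` and inserts `alt` immediately before `pos`. `contig_length`
#' is the length of the caller's assembled sequence supporting the call and
#' `flank_quality` the mapping quality of the contig's 5' flank.
#'
#' @param chrom,pos,ref,alt,contig_length,flank_quality,caller Column vectors,
#'   recycled to a common length.
#' @return A data.frame of class `variant_calls`.
#' @export
variant_calls <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          contig_length = integer(),
                          flank_quality = integer(),
                          caller = character()) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   contig_length = as.integer(contig_length),
                   flank_quality = as.integer(flank_quality),
                   caller = as.character(caller),
                   stringsAsFactors = FALSE)
  class(df) <- c("variant_calls", "data.frame")
  validate_calls(df)
}

validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  need <- c("chrom", "pos", "ref", "alt", "contig_length", "flank_quality")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("variant calls lack column(s): ", paste(miss, collapse = ", "))
  if (!nrow(calls)) return(calls)
  if (any(calls$pos < 1L)) stop("variant positions must be >= 1")
  if (any(!nzchar(calls$ref) & !nzchar(calls$alt)))
    stop("ref and alt alleles must not both be empty")
  span <- pmax(nchar(calls$ref), nchar(calls$alt))
  if (any(calls$contig_length < span))
    stop("contig_length must be >= max(len(ref), len(alt))")
  if (any(calls$flank_quality < 0L)) stop("flank_quality must be >= 0")
  calls
}

# Reference footprint of each call: deletions/substitutions span their ref
# allele; insertions have a zero-length footprint anchored at pos.
ref_span <- function(calls) {
  w <- nchar(calls$ref)
  data.frame(start = calls$pos, end = calls$pos + pmax(w, 1L) - 1L,
             zero = w == 0L)
}

#' Filter variant calls on 5'-flank mapping quality
#'
#' Drops calls whose assembled contig's 5' flank maps with quality below
#' `q_min` (strictly: calls with `flank_quality < q_min` are removed, so a
#' call at exactly `q_min` is kept). Input order is preserved.
#'
#' @param calls Variant-call data.frame.
#' @param q_min Minimum mapping quality (default 30).
#' @return The retained calls.
#' @export
filter_variants <- function(calls, q_min = 30) {
  calls <- validate_calls(calls)
  calls[calls$flank_quality >= q_min, , drop = FALSE]
}

#' Merge the outputs of two variant callers
#'
#' Two calls overlap when they share a chromosome and either have the same
#' position or their assembled-contig intervals `[pos, pos + contig_length)`
#' intersect. Each group of transitively overlapping calls is collapsed to
#' the single call with the longest assembled contig; ties keep the
#' bubble-caller record, then the leftmost, then the lexicographically
#' smaller alt allele. Output is sorted by chromosome and position.
#'
#' @param calls_a,calls_b Variant-call data.frames (each internally
#'   non-overlapping).
#' @return The merged, non-redundant call set.
#' @export
merge_caller_outputs <- function(calls_a, calls_b) {
  calls_a <- validate_calls(calls_a)
  calls_b <- validate_calls(calls_b)
  all <- rbind(as.data.frame(calls_a), as.data.frame(calls_b))
  if (!nrow(all)) {
    class(all) <- c("variant_calls", "data.frame")
    return(all)
  }
  # deterministic tie-break ordering within groups
  caller_rank <- ifelse(!is.na(all$caller) & all$caller == "bubble", 0L, 1L)
  keep <- logical(0)
  out <- all[0, , drop = FALSE]
  for (chrom in sort(unique(all$chrom))) {
    x <- all[all$chrom == chrom, , drop = FALSE]
    cr <- caller_rank[all$chrom == chrom]
    o <- order(x$pos, cr, x$alt)
    x <- x[o, , drop = FALSE]; cr <- cr[o]
    iv_start <- x$pos
    iv_end <- x$pos + x$contig_length - 1L   # inclusive contig interval
    # sweep: transitively overlapping contig intervals form one group
    grp <- integer(nrow(x)); g <- 0L; cur_end <- -1L
    for (i in seq_len(nrow(x))) {
      if (iv_start[i] > cur_end) { g <- g + 1L; cur_end <- iv_end[i] }
      else cur_end <- max(cur_end, iv_end[i])
      grp[i] <- g
    }
    pick <- vapply(split(seq_len(nrow(x)), grp), function(idx) {
      best <- idx[x$contig_length[idx] == max(x$contig_length[idx])]
      # rows already ordered by (pos, caller rank, alt) => first wins ties
      # but tie-break is bubble first, then leftmost, then smaller alt
      best[order(cr[best], x$pos[best], x$alt[best])][1]
    }, integer(1))
    out <- rbind(out, x[sort(pick), , drop = FALSE])
  }
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

# ---- apply & liftover ------------------------------------------------------

#' Apply variants to a reference genome
#'
#' Reconstructs a genotype's pseudo-genome by applying a sorted,
#' non-overlapping call set to the reference, and returns the coordinate map
#' between reference and reconstructed coordinates. Each call's `ref` allele
#' must match the reference sequence at its position; a mismatch aborts with
#' the chromosome and position. Calls whose reference footprints overlap are
#' rejected.
#'
#' @param reference An `annotated_genome` or named `DNAStringSet`.
#' @param calls Variant-call data.frame.
#' @return A list with `seqs` (named `DNAStringSet`) and `map`
#'   (`coordinate_map`).
#' @export
apply_variants <- function(reference, calls) {
  seqs <- if (inherits(reference, "annotated_genome")) reference$seqs else reference
  stopifnot(is(seqs, "DNAStringSet"))
  calls <- validate_calls(calls)
  bad <- setdiff(unique(calls$chrom), names(seqs))
  if (length(bad))
    stop("calls on unknown chromosome(s): ", paste(bad, collapse = ", "))
  out_seqs <- character(length(seqs))
  names(out_seqs) <- names(seqs)
  blocks <- list()
  for (chrom in names(seqs)) {
    refchr <- as.character(seqs[[chrom]])
    L <- nchar(refchr)
    x <- calls[calls$chrom == chrom, , drop = FALSE]
    x <- x[order(x$pos, nchar(x$ref)), , drop = FALSE]
    if (nrow(x)) {
      sp <- ref_span(x)
      # overlap check on true footprints (insertions allowed between bases)
      if (nrow(x) > 1L) {
        w <- nchar(x$ref)
        real_end <- x$pos + w - 1L           # end < pos for insertions
        prev_end <- cummax(c(-1L, real_end[-nrow(x)]))
        clash <- x$pos <= prev_end           # also catches an insertion
                                             # inside a deleted span
        if (any(clash))
          stop(sprintf("overlapping variants on %s near position %d",
                       chrom, x$pos[which(clash)[1]]))
      }
      if (any(x$pos + nchar(x$ref) - 1L > L) || any(x$pos > L + (nchar(x$ref) == 0L)))
        stop("variant beyond chromosome end on ", chrom)
      obs <- substring(refchr, x$pos, x$pos + nchar(x$ref) - 1L)
      mism <- which(obs != x$ref & nchar(x$ref) > 0L)
      if (length(mism))
        stop(sprintf("reference mismatch on %s at position %d: expected '%s', found '%s'",
                     chrom, x$pos[mism[1]], x$ref[mism[1]], obs[mism[1]]))
    }
    # splice: unchanged segments interleaved with alt alleles
    n <- nrow(x)
    seg_start <- c(1L, if (n) x$pos + nchar(x$ref))
    seg_end <- c(if (n) x$pos - 1L, L)
    segs <- substring(refchr, seg_start, pmax(seg_end, seg_start - 1L))
    pieces <- character(2L * n + 1L)
    pieces[seq(1L, 2L * n + 1L, by = 2L)] <- segs
    if (n) pieces[seq(2L, 2L * n, by = 2L)] <- x$alt
    out_seqs[[chrom]] <- paste(pieces, collapse = "")
    # coordinate blocks: maximal runs where target = ref + constant offset.
    # SNPs/MNVs do not break blocks; indels do.
    if (n) {
      delta <- nchar(x$alt) - nchar(x$ref)
      indel <- which(delta != 0L)
      bs <- 1L; off <- 0L; rs <- integer(0); re <- integer(0); os <- integer(0)
      for (k in indel) {
        be <- x$pos[k] - 1L                # block ends before the footprint
        if (be >= bs) { rs <- c(rs, bs); re <- c(re, be); os <- c(os, off) }
        # insertion resumes at pos itself; deletion (or mixed-length
        # substitution, treated as del+ins) resumes past the ref span
        bs <- x$pos[k] + nchar(x$ref[k])
        off <- off + delta[k]
      }
      if (bs <= L) { rs <- c(rs, bs); re <- c(re, L); os <- c(os, off) }
      if (length(rs))
        blocks[[chrom]] <- data.frame(chrom = chrom, ref_start = rs,
                                      ref_end = re, tgt_start = rs + os,
                                      tgt_end = re + os,
                                      stringsAsFactors = FALSE)
    } else {
      blocks[[chrom]] <- data.frame(chrom = chrom, ref_start = 1L, ref_end = L,
                                    tgt_start = 1L, tgt_end = L,
                                    stringsAsFactors = FALSE)
    }
  }
  bl <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  map <- structure(list(blocks = bl), class = "coordinate_map")
  attr(map, "ref_lengths") <- setNames(as.integer(lengths(seqs)), names(seqs))
  attr(map, "tgt_lengths") <- setNames(nchar(out_seqs), names(out_seqs))
  attr(map, "direction") <- "ref_to_target"
  list(seqs = Biostrings::DNAStringSet(out_seqs), map = map)
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat(sprintf("coordinate_map (%s): %d block(s) over %d chromosome(s)\n",
              attr(x, "direction"), nrow(x$blocks),
              length(unique(x$blocks$chrom))))
  invisible(x)
}

#' Lift positions through a coordinate map
#'
#' Maps reference positions to reconstructed-genotype positions (or the
#' reverse for an inverted map). Positions falling in unaligned gaps (deleted
#' reference bases, inserted genotype bases) lift to `NA`.
#'
#' @param map A `coordinate_map`.
#' @param chrom Chromosome names (recycled).
#' @param pos Positions to lift.
#' @return Integer vector of lifted positions, `NA` where unmapped.
#' @export
lift_positions <- function(map, chrom, pos) {
  stopifnot(inherits(map, "coordinate_map"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(as.integer(pos), n)
  out <- rep(NA_integer_, n)
  b <- map$blocks
  for (ch in unique(chrom)) {
    bc <- b[b$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (!nrow(bc)) next
    j <- findInterval(pos[idx], bc$ref_start)
    ok <- j >= 1L & pos[idx] <= ifelse(j >= 1L, bc$ref_end[pmax(j, 1L)], 0L)
    out[idx[ok]] <- pos[idx][ok] - bc$ref_start[j[ok]] + bc$tgt_start[j[ok]]
  }
  out
}

#' Invert a coordinate map
#' @param map A `coordinate_map`.
#' @return The map with reference and target roles swapped.
#' @export
invert_coordinate_map <- function(map) {
  stopifnot(inherits(map, "coordinate_map"))
  b <- map$blocks
  nb <- data.frame(chrom = b$chrom, ref_start = b$tgt_start,
                   ref_end = b$tgt_end, tgt_start = b$ref_start,
                   tgt_end = b$ref_end, stringsAsFactors = FALSE)
  out <- structure(list(blocks = nb), class = "coordinate_map")
  attr(out, "ref_lengths") <- attr(map, "tgt_lengths")
  attr(out, "tgt_lengths") <- attr(map, "ref_lengths")
  attr(out, "direction") <- if (identical(attr(map, "direction"), "ref_to_target"))
    "target_to_ref" else "ref_to_target"
  out
}

# ---- region classification -------------------------------------------------

#' Classify variants by genomic region and subgenome
#'
#' Assigns each variant exactly one region by the precedence
#' EXON > UTR > INTRON > INTERGENIC, evaluated at the variant's start
#' position (EXON means CDS-overlapping; UTRs are their own category).
#' Counts are grouped by the containing gene's subgenome; intergenic variants
#' take the nearest gene's subgenome; variants with no gene on the chromosome
#' (or an unlabeled gene) fall in the `unassigned` bucket. A variant's length
#' contribution is `max(len(ref), len(alt))`, so SNPs contribute 1 bp.
#'
#' @param calls Variant-call data.frame.
#' @param genome An `annotated_genome` with CDS and UTR sub-features.
#' @return A data.frame of class `region_counts` with columns `region`,
#'   `subgenome`, `count`, `length`; the per-variant assignment is attached
#'   as attribute `assignments`.
#' @export
classify_regions <- function(calls, genome) {
  calls <- validate_calls(calls)
  stopifnot(inherits(genome, "annotated_genome"))
  bad <- setdiff(unique(calls$chrom), names(genome$seqs))
  if (length(bad))
    stop("variant on unknown chromosome(s): ", paste(bad, collapse = ", "))
  f <- genome$features
  pts <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, calls$pos))
  hit_type <- function(type_set) {
    sub <- f[f$type %in% type_set]
    ov <- GenomicRanges::findOverlaps(pts, sub, ignore.strand = TRUE)
    res <- rep(NA_character_, length(pts))
    res[S4Vectors::queryHits(ov)] <- sub$gene_id[S4Vectors::subjectHits(ov)]
    res
  }
  in_cds <- hit_type("CDS")
  in_utr <- hit_type(c("five_prime_UTR", "three_prime_UTR"))
  in_gene <- hit_type("gene")
  region <- ifelse(!is.na(in_cds), "EXON",
            ifelse(!is.na(in_utr), "UTR",
            ifelse(!is.na(in_gene), "INTRON", "INTERGENIC")))
  owner <- ifelse(!is.na(in_cds), in_cds,
           ifelse(!is.na(in_utr), in_utr, in_gene))
  # intergenic: nearest gene's subgenome
  genes <- gene_ranges(genome)
  inter <- which(is.na(owner))
  if (length(inter) && length(genes)) {
    nr <- GenomicRanges::nearest(pts[inter], genes, ignore.strand = TRUE)
    owner[inter][!is.na(nr)] <- genes$gene_id[nr[!is.na(nr)]]
  }
  sg <- rep("unassigned", nrow(calls))
  known <- !is.na(owner)
  sg[known] <- unname(genome$subgenome[owner[known]])
  sg[is.na(sg)] <- "unassigned"
  len <- pmax(nchar(calls$ref), nchar(calls$alt), 1L)
  labels <- c(sort(unique(unname(genome$subgenome))), "unassigned")
  labels <- unique(c(setdiff(labels, "unassigned"), "unassigned"))
  regions <- c("EXON", "INTERGENIC", "INTRON", "UTR")
  grid <- expand.grid(region = regions, subgenome = labels,
                      stringsAsFactors = FALSE)
  key <- paste(region, sg)
  agg_count <- tapply(rep(1L, length(key)), key, sum)
  agg_len <- tapply(len, key, sum)
  gk <- paste(grid$region, grid$subgenome)
  grid$count <- as.integer(ifelse(is.na(agg_count[gk]), 0L, agg_count[gk]))
  grid$length <- as.integer(ifelse(is.na(agg_len[gk]), 0L, agg_len[gk]))
  class(grid) <- c("region_counts", "data.frame")
  attr(grid, "assignments") <- data.frame(
    chrom = calls$chrom, pos = calls$pos, region = region,
    subgenome = sg, gene_id = owner, length = len, stringsAsFactors = FALSE)
  grid
}
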