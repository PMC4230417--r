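#' Annotate coding effects of variants on gene models
#'
#' For every (variant, overlapping gene) pair, reports the single most severe
#' applicable category in the fixed order
#' `EXON_DELETED > FRAME_SHIFT > STOP_GAINED > STOP_LOST > START_LOST >
#' SPLICE_SITE_ACCEPTOR > SPLICE_SITE_DONOR > NONE`. Codon evaluation is
#' strand-aware: the mutant spliced CDS is rebuilt and translated. Splice
#' sites are the first and last two intronic bases (GT/AG convention). Genes
#' whose reference CDS length is not a multiple of three raise a validation
#' warning and are skipped.
#'
#' @param calls Variant-call data.frame.
#' @param genome An `annotated_genome` with CDS sub-features.
#' @return A data.frame (`chrom`, `pos`, `ref`, `alt`, `gene_id`, `category`),
#'   one row per variant-gene pair.
#' @export
annotate_effects <- function(calls, genome) {
  calls <- validate_calls(calls)
  stopifnot(inherits(genome, "annotated_genome"))
  severities <- c("EXON_DELETED", "FRAME_SHIFT", "STOP_GAINED", "STOP_LOST",
                  "START_LOST", "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR",
                  "NONE")
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene_id = character(),
                      category = character(), stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  genes <- gene_ranges(genome)
  if (!length(genes)) return(empty)
  # variant footprint: insertions are anchored between pos-1 and pos
  is_ins <- nchar(calls$ref) == 0L
  v_start <- ifelse(is_ins, pmax(calls$pos - 1L, 1L), calls$pos)
  v_end <- ifelse(is_ins, calls$pos, calls$pos + nchar(calls$ref) - 1L)
  vr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(v_start, v_end))
  ov <- GenomicRanges::findOverlaps(vr, genes, ignore.strand = TRUE)
  rows <- list()
  gene_cache <- new.env(parent = emptyenv())
  for (k in seq_along(ov)) {
    vi <- S4Vectors::queryHits(ov)[k]
    gi <- S4Vectors::subjectHits(ov)[k]
    gid <- genes$gene_id[gi]
    mod <- gene_model_cached(gene_cache, genome, gid)
    if (is.null(mod)) next   # invalid reference model, warned already
    cat_ <- classify_effect(calls[vi, ], mod)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = calls$chrom[vi], pos = calls$pos[vi], ref = calls$ref[vi],
      alt = calls$alt[vi], gene_id = gid, category = cat_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out$category <- factor(out$category, levels = severities)
  out$category <- as.character(out$category)
  out
}

# cached per-gene model: CDS intervals, exons, introns, splice sites, the
# reference spliced CDS and protein
gene_model_cached <- function(cache, genome, gid) {
  if (!is.null(cache[[gid]])) {
    if (identical(cache[[gid]], "invalid")) return(NULL)
    return(cache[[gid]])
  }
  iv <- cds_intervals(genome, gid)
  if (is.null(iv)) { cache[[gid]] <- "invalid"; return(NULL) }
  cds_len <- sum(iv$end - iv$start + 1L)
  if (cds_len %% 3L != 0L) {
    warning("model-validation: CDS length of ", gid,
            " is not a multiple of 3; gene skipped")
    cache[[gid]] <- "invalid"
    return(NULL)
  }
  f <- genome$features
  ex <- f[f$type == "exon" & f$gene_id == gid]
  es <- sort(BiocGenerics::start(ex)); ee <- sort(BiocGenerics::end(ex))
  introns <- if (length(es) > 1L)
    data.frame(start = ee[-length(ee)] + 1L, end = es[-1L] - 1L)
  else data.frame(start = integer(), end = integer())
  strand <- iv$strand[1]
  # donor = intron end adjacent to the upstream exon (5' of the intron in
  # transcription direction); acceptor = 3' end
  splice <- NULL
  if (nrow(introns)) {
    left <- data.frame(start = introns$start, end = introns$start + 1L)
    right <- data.frame(start = introns$end - 1L, end = introns$end)
    if (strand == "+") {
      left$site <- "SPLICE_SITE_DONOR"; right$site <- "SPLICE_SITE_ACCEPTOR"
    } else {
      left$site <- "SPLICE_SITE_ACCEPTOR"; right$site <- "SPLICE_SITE_DONOR"
    }
    splice <- rbind(left, right)
  }
  cds_seq <- spliced_cds(genome, gid)
  mod <- list(gid = gid, strand = strand, iv = iv,
              exons = data.frame(start = es, end = ee),
              splice = splice, cds = cds_seq,
              protein = translate_chr(cds_seq))
  cache[[gid]] <- mod
  mod
}

# genomic position -> 1-based coordinate in the spliced CDS (coding strand),
# NA when outside the CDS
cds_coord <- function(mod, pos) {
  iv <- mod$iv   # already in translation order
  off <- 0L
  for (i in seq_len(nrow(iv))) {
    if (pos >= iv$start[i] && pos <= iv$end[i]) {
      return(if (mod$strand == "+") off + (pos - iv$start[i] + 1L)
             else off + (iv$end[i] - pos + 1L))
    }
    off <- off + iv$end[i] - iv$start[i] + 1L
  }
  NA_integer_
}

classify_effect <- function(call, mod) {
  ref <- call$ref; alt <- call$alt; pos <- call$pos
  is_ins <- nchar(ref) == 0L
  v_end <- if (is_ins) pos - 1L else pos + nchar(ref) - 1L

  # EXON_DELETED: a deletion-like variant whose ref span covers a whole exon
  if (nchar(ref) > nchar(alt)) {
    covered <- any(pos <= mod$exons$start & v_end >= mod$exons$end)
    if (covered) return("EXON_DELETED")
  }

  # portion of the variant inside the CDS (genomic coordinates)
  cds_hit <- FALSE; del_in_cds <- 0L; ins_in_cds <- 0L
  ref_positions <- if (is_ins) integer(0) else pos:v_end
  in_cds <- if (length(ref_positions))
    vapply(ref_positions, function(p) !is.na(cds_coord(mod, p)), logical(1))
  else logical(0)
  if (is_ins) {
    # an insertion interrupts the CDS when both flanking bases are coding
    c1 <- cds_coord(mod, pos - 1L); c2 <- cds_coord(mod, pos)
    if (!is.na(c1) && !is.na(c2) && abs(c1 - c2) == 1L) {
      cds_hit <- TRUE; ins_in_cds <- nchar(alt)
    }
  } else if (any(in_cds)) {
    cds_hit <- TRUE
    if (nchar(ref) == nchar(alt)) {
      # substitution: no length change
    } else {
      del_in_cds <- sum(in_cds)
      ins_in_cds <- if (all(in_cds)) nchar(alt) else 0L
    }
  }
  net <- ins_in_cds - del_in_cds
  if (cds_hit && net %% 3L != 0L) return("FRAME_SHIFT")

  cand <- character(0)
  if (cds_hit) {
    mut <- mutant_cds(mod, call)
    if (!is.null(mut) && nchar(mut) >= 3L && nchar(mut) %% 3L == 0L) {
      aa_ref <- mod$protein
      aa_mut <- translate_chr(mut)
      n_mut <- nchar(aa_mut)
      first_stop <- regexpr("*", aa_mut, fixed = TRUE)
      if (first_stop > 0L && first_stop < n_mut) cand <- c(cand, "STOP_GAINED")
      if (substr(aa_mut, n_mut, n_mut) != "*" &&
          substr(aa_ref, nchar(aa_ref), nchar(aa_ref)) == "*")
        cand <- c(cand, "STOP_LOST")
      if (substr(aa_mut, 1L, 1L) != "M") cand <- c(cand, "START_LOST")
    }
  }
  if (!is.null(mod$splice) && nrow(mod$splice)) {
    hit <- if (is_ins) {
      # an insertion disrupts a splice site only when it lands between the
      # two bases of the dinucleotide
      mod$splice$site[mod$splice$start < pos & mod$splice$end >= pos]
    } else {
      mod$splice$site[mod$splice$start <= v_end & mod$splice$end >= pos]
    }
    cand <- c(cand, hit)
  }
  for (sev in c("STOP_GAINED", "STOP_LOST", "START_LOST",
                "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR"))
    if (sev %in% cand) return(sev)
  "NONE"
}

# rebuild the spliced CDS with the variant applied (coding-strand sequence)
mutant_cds <- function(mod, call) {
  chars <- strsplit(mod$cds, "")[[1]]
  pos <- call$pos; ref <- call$ref; alt <- call$alt
  plus <- mod$strand == "+"
  if (nchar(ref) == 0L) {                       # insertion
    c1 <- cds_coord(mod, pos - 1L); c2 <- cds_coord(mod, pos)
    if (is.na(c1) || is.na(c2)) return(NULL)
    at <- min(c1, c2)                           # insert after CDS coord `at`
    insseq <- if (plus) alt else revcomp_chr(alt)
    return(paste0(paste(chars[seq_len(at)], collapse = ""), insseq,
                  paste(chars[seq(at + 1L, length(chars))], collapse = "")))
  }
  gpos <- pos:(pos + nchar(ref) - 1L)
  cpos <- vapply(gpos, function(p) cds_coord(mod, p), integer(1))
  inside <- !is.na(cpos)
  if (!any(inside)) return(mod$cds)
  if (nchar(ref) == nchar(alt)) {               # substitution, 1:1 bases
    altchars <- strsplit(alt, "")[[1]]
    for (i in which(inside)) {
      b <- altchars[i]
      chars[cpos[i]] <- if (plus) b else revcomp_chr(b)
    }
    return(paste(chars, collapse = ""))
  }
  # deletion (or mixed-length substitution treated as del+ins): remove the
  # in-CDS ref bases; splice the alt in only when the whole ref span is coding
  drop_idx <- cpos[inside]
  keep <- setdiff(seq_along(chars), drop_idx)
  base <- chars[keep]
  if (all(inside) && nchar(alt) > 0L) {
    at <- min(cpos) - 1L
    insseq <- if (plus) alt else revcomp_chr(alt)
    return(paste0(paste(base[seq_len(at)], collapse = ""), insseq,
                  paste(base[seq(at + 1L, length(base))], collapse = "")))
  }
  paste(base, collapse = "")
}

#' Count genes functionally affected by variants
#'
#' A gene is affected when at least one variant receives a non-`NONE`
#' category; each gene counts once regardless of how many variants hit it.
#'
#' @param effects Output of [annotate_effects()], optionally with an extra
#'   `genotype` column.
#' @return If a `genotype` column is present, a data.frame of per-genotype
#'   counts; otherwise a single integer.
#' @export
count_affected_genes <- function(effects) {
  hit <- effects[effects$category != "NONE", , drop = FALSE]
  if ("genotype" %in% names(effects)) {
    gt <- sort(unique(effects$genotype))
    data.frame(genotype = gt,
               affected_genes = vapply(gt, function(g)
                 length(unique(hit$gene_id[hit$genotype == g])), integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    length(unique(hit$gene_id))
  }
}
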