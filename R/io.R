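#' @title File input/output for pipeline artifacts
#' @description Readers and writers for FASTA, GFF3, VCF (with the caller
#'   INFO keys `CONTIGLEN`, `FLANKQ`, `CALLER`), UCSC chain files and TSV
#'   tables. Coordinates are 1-based inclusive at every file interface.
#' @name pangenekit-io
NULL

#' Read a genome FASTA file
#' @param path FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a genome FASTA file
#' @param seqs Named `DNAStringSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a proteome FASTA file
#' @param path FASTA file.
#' @return A named `AAStringSet`.
#' @export
read_proteome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a proteome FASTA file
#' @param seqs Named `AAStringSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Validates coordinates before parsing (start/end must be positive integers
#' with start <= end) and reports offending lines, then delegates parsing to
#' rtracklayer.
#'
#' @param path GFF3 file.
#' @return A `GRanges` with `type`, `ID`, `Parent`, `gene_id`, `phase`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(data_idx)) {
    fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9L))
      stop(sprintf("parse error in %s line %d: expected 9 tab-separated fields",
                   path, data_idx[which(nf != 9L)[1]]))
    starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
    ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
    bad <- which(is.na(starts) | is.na(ends) | starts < 1L | ends < starts)
    if (length(bad))
      stop(sprintf("parse error in %s line %d: invalid coordinates '%s'..'%s'",
                   path, data_idx[bad[1]], fields[[bad[1]]][4], fields[[bad[1]]][5]))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  gene_id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
             else rep(NA_character_, length(gr))
  phase <- if ("phase" %in% names(mc)) as.integer(mc$phase)
           else rep(NA_integer_, length(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = as.character(mc$type), ID = as.character(mc$ID),
    Parent = parent, gene_id = gene_id, phase = phase)
  gr
}

#' Write gene models to GFF3
#' @param features `GRanges` with `type`, `ID`, `Parent`, `gene_id`, `phase`.
#' @param path Output file.
#' @param seq_lengths Optional named integer vector for `##sequence-region`
#'   directives.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seq_lengths = NULL) {
  gr <- features
  mc <- S4Vectors::mcols(gr)
  parent <- mc$Parent
  pl <- as.list(parent)
  pl[is.na(parent)] <- list(character(0))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = mc$type, ID = mc$ID,
    Parent = IRanges::CharacterList(pl),
    gene_id = mc$gene_id,
    phase = mc$phase)
  if (!is.null(seq_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seq_lengths)
    GenomeInfoDb::seqlengths(gr) <- seq_lengths
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---- VCF -------------------------------------------------------------------

# Internal allele convention: SNP/MNV have equal-length ref/alt; a deletion
# has alt == "" and removes ref positions pos..pos+nchar(ref)-1; an insertion
# has ref == "" and inserts alt immediately BEFORE reference position pos.
# On disk the usual VCF left-anchored representation is used.

#' Write variant calls to VCF
#'
#' Indels are left-anchored on the preceding reference base, as usual in VCF;
#' the caller metadata travel in the INFO keys `CONTIGLEN` (assembled contig
#' length), `FLANKQ` (5'-flank mapping quality) and `CALLER`.
#'
#' @param calls Variant-call data.frame (see [variant_calls()]).
#' @param ref_seqs Named `DNAStringSet` of the reference (needed for anchor
#'   bases).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, ref_seqs, path) {
  calls <- validate_calls(calls)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(ref_seqs),
                   lengths(ref_seqs)),
           "##INFO=<ID=CONTIGLEN,Number=1,Type=Integer,Description=\"Length of the assembled contig supporting the call\">",
           "##INFO=<ID=FLANKQ,Number=1,Type=Integer,Description=\"Mapping quality of the contig 5-prime flank\">",
           "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Variant caller\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  n <- nrow(calls)
  pos <- integer(n); ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    r <- calls$ref[i]; a <- calls$alt[i]; p <- calls$pos[i]
    if (nchar(r) == nchar(a)) {          # SNP / MNV
      pos[i] <- p; ref[i] <- r; alt[i] <- a
    } else {                             # anchored indel (or mixed length)
      if (p < 2L)
        stop("cannot left-anchor variant at position 1 on ", calls$chrom[i])
      anchor <- substr(as.character(ref_seqs[[calls$chrom[i]]]), p - 1L, p - 1L)
      pos[i] <- p - 1L
      ref[i] <- paste0(anchor, r)
      alt[i] <- paste0(anchor, a)
    }
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tCONTIGLEN=%d;FLANKQ=%d;CALLER=%s",
                  calls$chrom, pos, ref, alt,
                  calls$contig_length, calls$flank_quality, calls$caller)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variant calls from VCF
#'
#' Parses with VariantAnnotation and converts left-anchored indels back to
#' the internal un-anchored representation. The INFO keys `CONTIGLEN` and
#' `FLANKQ` are required.
#'
#' @param path VCF file.
#' @return A variant-call data.frame (see [variant_calls()]).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  for (key in c("CONTIGLEN", "FLANKQ"))
    if (!key %in% names(info))
      stop("validation error in ", path, ": missing INFO key ", key)
  if (nrow(info) && (anyNA(info$CONTIGLEN) || anyNA(info$FLANKQ)))
    stop("validation error in ", path, ": empty CONTIGLEN/FLANKQ values")
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                function(a) as.character(a)[1], character(1))
  pos <- BiocGenerics::start(rr)
  out_pos <- integer(n); out_ref <- character(n); out_alt <- character(n)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    if (nchar(r) == nchar(a)) {
      out_pos[i] <- pos[i]; out_ref[i] <- r; out_alt[i] <- a
    } else if (substr(r, 1, 1) == substr(a, 1, 1)) {
      out_pos[i] <- pos[i] + 1L
      out_ref[i] <- substr(r, 2, nchar(r))
      out_alt[i] <- substr(a, 2, nchar(a))
    } else {
      out_pos[i] <- pos[i]; out_ref[i] <- r; out_alt[i] <- a
    }
  }
  caller <- if ("CALLER" %in% names(info)) as.character(info$CALLER)
            else rep(NA_character_, n)
  variant_calls(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                pos = out_pos, ref = out_ref, alt = out_alt,
                contig_length = as.integer(info$CONTIGLEN),
                flank_quality = as.integer(info$FLANKQ),
                caller = caller)
}

# ---- chain -----------------------------------------------------------------

#' Write a coordinate map as a UCSC chain file
#'
#' The reference is the chain target and the reconstructed genotype the
#' query; both on the + strand.
#'
#' @param map A `coordinate_map` (see [apply_variants()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chain <- function(map, path) {
  stopifnot(inherits(map, "coordinate_map"))
  blocks <- map$blocks
  ref_len <- attr(map, "ref_lengths")
  tgt_len <- attr(map, "tgt_lengths")
  out <- character(0)
  id <- 0L
  for (chrom in names(ref_len)) {
    b <- blocks[blocks$chrom == chrom, , drop = FALSE]
    if (!nrow(b)) next
    id <- id + 1L
    score <- sum(b$ref_end - b$ref_start + 1L)
    out <- c(out, sprintf("chain %d %s %d + %d %d %s %d + %d %d %d",
                          score, chrom, ref_len[[chrom]],
                          b$ref_start[1] - 1L, b$ref_end[nrow(b)],
                          chrom, tgt_len[[chrom]],
                          b$tgt_start[1] - 1L, b$tgt_end[nrow(b)], id))
    sizes <- b$ref_end - b$ref_start + 1L
    if (nrow(b) > 1L) {
      dt <- b$ref_start[-1L] - b$ref_end[-nrow(b)] - 1L
      dq <- b$tgt_start[-1L] - b$tgt_end[-nrow(b)] - 1L
      out <- c(out, sprintf("%d\t%d\t%d", sizes[-nrow(b)], dt, dq))
    }
    out <- c(out, sprintf("%d", sizes[nrow(b)]), "")
  }
  writeLines(out, path)
  invisible(path)
}

# ---- TSV -------------------------------------------------------------------

#' Write a data.frame as TSV
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input file.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
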