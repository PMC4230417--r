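#' Annotated genome container
#'
#' Bundles chromosome sequences, hierarchical gene models and per-gene
#' subgenome labels. Features follow GFF3 conventions: types `gene`, `mRNA`,
#' `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`; 1-based inclusive
#' coordinates; `ID`/`Parent` links; CDS carry a `phase`.
#'
#' @param seqs A named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param features A [GenomicRanges::GRanges] with metadata columns `type`,
#'   `ID`, `Parent` (character), `gene_id` and `phase` (integer, `NA` outside
#'   CDS).
#' @param subgenome Named character vector mapping gene ids to subgenome
#'   labels (`LF`, `MF1`, `MF2` or `unassigned`). Missing genes default to
#'   `unassigned`.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(seqs, features, subgenome = NULL) {
  stopifnot(is(seqs, "DNAStringSet"), is(features, "GRanges"))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("chromosome sequences must have unique names")
  need <- c("type", "ID", "gene_id")
  miss <- setdiff(need, names(S4Vectors::mcols(features)))
  if (length(miss))
    stop("features lack metadata column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(as.character(GenomeInfoDb::seqnames(features)), names(seqs))
  if (length(bad))
    stop("features on unknown chromosome(s): ", paste(unique(bad), collapse = ", "))
  gid <- unique(features$gene_id[features$type == "gene"])
  sg <- setNames(rep("unassigned", length(gid)), gid)
  if (!is.null(subgenome)) {
    keep <- intersect(names(subgenome), gid)
    sg[keep] <- subgenome[keep]
  }
  structure(list(seqs = seqs, features = features, subgenome = sg),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome: %d chromosome(s), %s bp, %d gene(s)\n",
              length(x$seqs), format(sum(lengths(x$seqs)), big.mark = ","),
              sum(x$features$type == "gene")))
  tab <- table(x$subgenome)
  cat("  subgenomes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Gene-level ranges of an annotated genome
#'
#' @param genome An `annotated_genome`.
#' @return A `GRanges` of `gene` features (one range per gene, with `gene_id`
#'   and `subgenome` metadata).
#' @export
gene_ranges <- function(genome) {
  g <- genome$features[genome$features$type == "gene"]
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    gene_id = g$gene_id,
    subgenome = unname(genome$subgenome[g$gene_id]))
  g
}

#' Exon ranges of an annotated genome
#'
#' @param genome An `annotated_genome`.
#' @return A `GRanges` of `exon` features with `gene_id` metadata.
#' @export
exon_ranges <- function(genome) {
  g <- genome$features[genome$features$type == "exon"]
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(gene_id = g$gene_id)
  g
}

#' Gene table of an annotated genome
#'
#' @param genome An `annotated_genome`.
#' @return A data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `subgenome`, ordered by chromosome and start.
#' @export
gene_table <- function(genome) {
  g <- gene_ranges(genome)
  df <- data.frame(gene_id = g$gene_id,
                   chrom = as.character(GenomeInfoDb::seqnames(g)),
                   start = BiocGenerics::start(g),
                   end = BiocGenerics::end(g),
                   strand = as.character(BiocGenerics::strand(g)),
                   subgenome = g$subgenome,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# CDS intervals of one gene in translation order (5' first for the coding
# strand), as a data.frame chrom/start/end/strand.
cds_intervals <- function(genome, gene_id) {
  f <- genome$features
  cds <- f[f$type == "CDS" & f$gene_id == gene_id]
  if (!length(cds)) return(NULL)
  o <- order(BiocGenerics::start(cds))
  cds <- cds[o]
  minus <- as.character(BiocGenerics::strand(cds)[1]) == "-"
  if (minus) cds <- rev(cds)
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(cds)),
             start = BiocGenerics::start(cds),
             end = BiocGenerics::end(cds),
             strand = as.character(BiocGenerics::strand(cds)),
             stringsAsFactors = FALSE)
}

# Spliced CDS sequence of one gene as a character scalar (coding strand).
spliced_cds <- function(genome, gene_id) {
  iv <- cds_intervals(genome, gene_id)
  if (is.null(iv)) return(NULL)
  chrom <- as.character(genome$seqs[[iv$chrom[1]]])
  parts <- substring(chrom, iv$start, iv$end)
  if (iv$strand[1] == "-")
    parts <- vapply(parts, revcomp_chr, character(1), USE.NAMES = FALSE)
  paste(parts, collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# codon-table translation (standard code); unknown codons become X
translate_chr <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# flat data.frame of the CDS features (one pass over the GRanges)
cds_table <- function(genome) {
  f <- genome$features
  sel <- which(f$type == "CDS")
  fs <- f[sel]
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(fs)),
             start = BiocGenerics::start(fs),
             end = BiocGenerics::end(fs),
             strand = as.character(BiocGenerics::strand(fs)),
             gene_id = fs$gene_id, stringsAsFactors = FALSE)
}

# spliced coding-strand CDS for every gene at once, named by gene id
spliced_cds_all <- function(genome) {
  cds <- cds_table(genome)
  if (!nrow(cds)) return(setNames(character(0), character(0)))
  chrom_str <- setNames(as.character(genome$seqs), names(genome$seqs))
  cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
  parts <- substring(chrom_str[cds$chrom], cds$start, cds$end)
  plus_seq <- vapply(split(parts, cds$gene_id), paste, character(1),
                     collapse = "")
  strand_of <- tapply(cds$strand, cds$gene_id, `[`, 1L)
  minus <- names(plus_seq)[strand_of[names(plus_seq)] == "-"]
  if (length(minus))
    plus_seq[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(plus_seq[minus])))
  plus_seq
}

#' Extract the proteome of an annotated genome
#'
#' Splices each gene's CDS in genomic order (strand-aware), translates it and
#' trims at the first stop codon. Genes whose CDS length is not a multiple of
#' three are translated up to the last complete codon.
#'
#' @param genome An `annotated_genome`.
#' @return A named [Biostrings::AAStringSet], one protein per gene.
#' @export
extract_proteins <- function(genome) {
  cds <- spliced_cds_all(genome)
  gids <- gene_table(genome)$gene_id
  cds <- cds[intersect(gids, names(cds))]
  prots <- vapply(cds, function(s) {
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) return("")
    aa <- translate_chr(substr(s, 1L, n))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0L) aa <- substr(aa, 1L, stop_at - 1L)
    aa
  }, character(1))
  Biostrings::AAStringSet(prots[nchar(prots) > 0L])
}
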