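#' Protein similarity by local alignment
#'
#' Smith-Waterman local alignment with BLOSUM62 and affine gaps (a gap of
#' length L costs `gap_open + L * gap_ext`). The score is symmetric;
#' `identity` is the fraction of identical columns in the optimal local
#' alignment.
#'
#' @param protein_a,protein_b Amino-acid sequences (character or `AAString`).
#' @param gap_open,gap_ext Gap penalties (defaults 11 and 1).
#' @param submat Substitution matrix (default [blosum62()]).
#' @return A one-row data.frame with `score` and `identity`.
#' @export
score_similarity <- function(protein_a, protein_b, gap_open = 11L,
                             gap_ext = 1L, submat = blosum62()) {
  a <- toupper(as.character(protein_a)); b <- toupper(as.character(protein_b))
  if (!nzchar(a) || !nzchar(b))
    stop("validation error: empty protein sequence")
  st <- .sw_align_stats(a, b, submat, as.integer(gap_open),
                        as.integer(gap_ext))
  data.frame(score = st$score,
             identity = if (st$columns > 0L) st$matches / st$columns else 0)
}

#' All-vs-all local-alignment score matrix
#'
#' @param set_a,set_b Named `AAStringSet`s (or named character vectors).
#' @inheritParams score_similarity
#' @return A numeric matrix of scores, rows = `set_a`, columns = `set_b`.
#' @export
similarity_matrix <- function(set_a, set_b, gap_open = 11L, gap_ext = 1L,
                              submat = blosum62()) {
  a <- toupper(as.character(set_a)); b <- toupper(as.character(set_b))
  if (!length(a) || !length(b))
    return(matrix(numeric(0), length(a), length(b),
                  dimnames = list(names(a), names(b))))
  m <- .sw_score_matrix(a, b, submat, as.integer(gap_open),
                        as.integer(gap_ext))
  dimnames(m) <- list(names(a), names(b))
  m
}

# unique (tie-free) best column per row, NA where tied or below floor
best_hits <- function(score_mat, score_floor) {
  n <- nrow(score_mat)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    row <- score_mat[i, ]
    mx <- max(row)
    if (mx < score_floor) next
    w <- which(row == mx)
    if (length(w) == 1L) out[i] <- w
  }
  out
}

#' Reciprocal best hits between two proteomes
#'
#' `(a, b)` is a pair when `b` is `a`'s unique best-scoring hit in set B and
#' `a` is `b`'s unique best in set A, with score at least `score_floor`.
#' Score ties for "best" break uniqueness, so a tied gene forms no pair.
#'
#' @param set_a,set_b Named `AAStringSet`s.
#' @param score_floor Minimum alignment score (default 50).
#' @param scores Optional precomputed score matrix from
#'   [similarity_matrix()].
#' @inheritParams score_similarity
#' @return A data.frame with `gene_a`, `gene_b`, `score`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, score_floor = 50,
                                 gap_open = 11L, gap_ext = 1L,
                                 submat = blosum62(), scores = NULL) {
  if (is.null(scores))
    scores <- similarity_matrix(set_a, set_b, gap_open, gap_ext, submat)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!nrow(scores) || !ncol(scores)) return(empty)
  best_ab <- best_hits(scores, score_floor)
  best_ba <- best_hits(t(scores), score_floor)
  ia <- which(!is.na(best_ab))
  mutual <- ia[!is.na(best_ba[best_ab[ia]]) & best_ba[best_ab[ia]] == ia]
  if (!length(mutual)) return(empty)
  data.frame(gene_a = rownames(scores)[mutual],
             gene_b = colnames(scores)[best_ab[mutual]],
             score = scores[cbind(mutual, best_ab[mutual])],
             stringsAsFactors = FALSE)
}

#' Positional orthologs between two annotated genomes
#'
#' Reciprocal best hits between the two proteomes, retained only when both
#' genes lie on the same-named chromosome or scaffold (the genomes are
#' reference-anchored, so sequence names correspond).
#'
#' @param genome_a,genome_b `annotated_genome` objects.
#' @param proteome_a,proteome_b Optional precomputed proteomes
#'   ([extract_proteins()]).
#' @inheritParams reciprocal_best_hits
#' @return A data.frame with `gene_a`, `gene_b`, `chrom`, `score`.
#' @export
positional_orthologs <- function(genome_a, genome_b, score_floor = 50,
                                 proteome_a = NULL, proteome_b = NULL,
                                 scores = NULL) {
  if (is.null(proteome_a)) proteome_a <- extract_proteins(genome_a)
  if (is.null(proteome_b)) proteome_b <- extract_proteins(genome_b)
  rbh <- reciprocal_best_hits(proteome_a, proteome_b,
                              score_floor = score_floor, scores = scores)
  ta <- gene_table(genome_a); tb <- gene_table(genome_b)
  chrom_a <- ta$chrom[match(rbh$gene_a, ta$gene_id)]
  chrom_b <- tb$chrom[match(rbh$gene_b, tb$gene_id)]
  keep <- !is.na(chrom_a) & !is.na(chrom_b) & chrom_a == chrom_b
  out <- rbh[keep, , drop = FALSE]
  out$chrom <- chrom_a[keep]
  rownames(out) <- NULL
  out
}

#' Ortholog copy counts against an outgroup proteome
#'
#' Every genome gene is assigned to its unique best-scoring outgroup gene
#' (ties or scores below `score_floor` leave it unassigned). The copy count
#' of outgroup gene `g` is the number of assigned genome genes whose score
#' reaches `inclusion_ratio` times the score of `g`'s best genome hit -- a
#' best-hit cluster rule that reproduces 1:many ortholog counting.
#'
#' @param outgroup Named `AAStringSet` of outgroup proteins.
#' @param genome An `annotated_genome` (or a named `AAStringSet` proteome).
#' @param inclusion_ratio Score ratio for cluster membership (default 0.8).
#' @param score_floor Minimum alignment score (default 50).
#' @param scores Optional precomputed matrix (genome genes x outgroup genes).
#' @return A data.frame with `outgroup_gene` and `count`.
#' @export
ortholog_copy_counts <- function(outgroup, genome, inclusion_ratio = 0.8,
                                 score_floor = 50, scores = NULL) {
  prot <- if (inherits(genome, "annotated_genome")) extract_proteins(genome)
          else genome
  if (is.null(scores)) scores <- similarity_matrix(prot, outgroup)
  counts <- setNames(rep(0L, length(outgroup)), names(outgroup))
  if (nrow(scores) && ncol(scores)) {
    assign <- best_hits(scores, score_floor)
    for (j in seq_len(ncol(scores))) {
      members <- which(!is.na(assign) & assign == j)
      if (!length(members)) next
      top <- max(scores[, j])
      counts[j] <- sum(scores[cbind(members, j)] >= inclusion_ratio * top)
    }
  }
  data.frame(outgroup_gene = names(counts), count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
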