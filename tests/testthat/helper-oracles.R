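# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: closures by breadth-first search instead of a sweep,
# right-to-left string edits instead of segment splicing, Biostrings
# alignments instead of the compiled scorer, and quadratic interval loops.

# ---- caller merge ----------------------------------------------------------

# overlap: same chromosome and (same position OR contig intervals intersect);
# adjacency built by all-pairs outer comparison, components by BFS
oracle_merge <- function(calls_a, calls_b) {
  all <- rbind(as.data.frame(calls_a), as.data.frame(calls_b))
  n <- nrow(all)
  if (n == 0L) return(all)
  ends <- all$pos + all$contig_length - 1L
  adj_mat <- outer(all$chrom, all$chrom, "==") &
    (outer(all$pos, all$pos, "==") |
       (outer(all$pos, ends, "<=") & t(outer(all$pos, ends, "<="))))
  diag(adj_mat) <- FALSE
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj_mat[v, ] & is.na(comp)))
    }
  }
  picks <- vapply(split(seq_len(n), comp), function(idx) {
    best <- idx[all$contig_length[idx] == max(all$contig_length[idx])]
    rank <- order(ifelse(!is.na(all$caller[best]) &
                           all$caller[best] == "bubble", 0L, 1L),
                  all$pos[best], all$alt[best])
    best[rank][1]
  }, integer(1))
  out <- all[picks, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- apply variants --------------------------------------------------------

# edit a chromosome string right-to-left so earlier coordinates stay valid
oracle_apply_chrom <- function(refchr, calls) {
  x <- calls[order(-calls$pos), , drop = FALSE]
  s <- refchr
  for (i in seq_len(nrow(x))) {
    p <- x$pos[i]; ref <- x$ref[i]; alt <- x$alt[i]
    if (nchar(ref) == 0L) {
      s <- paste0(substr(s, 1L, p - 1L), alt, substr(s, p, nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, p - 1L), alt,
                  substr(s, p + nchar(ref), nchar(s)))
    }
  }
  s
}

# ---- region classification -------------------------------------------------

oracle_region_of <- function(genome, chrom, pos) {
  f <- genome$features
  fd <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(f)),
                   start = BiocGenerics::start(f),
                   end = BiocGenerics::end(f),
                   type = f$type, gene_id = f$gene_id,
                   stringsAsFactors = FALSE)
  at <- function(types) {
    hit <- fd$chrom == chrom & fd$start <= pos & fd$end >= pos &
      fd$type %in% types
    if (any(hit)) fd$gene_id[which(hit)[1]] else NA_character_
  }
  g <- at("CDS")
  if (!is.na(g)) return(list(region = "EXON", gene = g))
  g <- at(c("five_prime_UTR", "three_prime_UTR"))
  if (!is.na(g)) return(list(region = "UTR", gene = g))
  g <- at("gene")
  if (!is.na(g)) return(list(region = "INTRON", gene = g))
  genes <- fd[fd$type == "gene" & fd$chrom == chrom, , drop = FALSE]
  if (!nrow(genes)) return(list(region = "INTERGENIC", gene = NA_character_))
  d <- pmax(genes$start - pos, pos - genes$end, 0L)
  list(region = "INTERGENIC", gene = genes$gene_id[which.min(d)])
}

# ---- alignment -------------------------------------------------------------

oracle_sw_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  BiocGenerics::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_ext))
}

# all-vs-all score matrix through Biostrings (vectorised over patterns)
oracle_sw_matrix <- function(set_a, set_b, gap_open = 11, gap_ext = 1) {
  m <- matrix(0, length(set_a), length(set_b),
              dimnames = list(names(set_a), names(set_b)))
  for (j in seq_along(set_b)) {
    m[, j] <- BiocGenerics::score(Biostrings::pairwiseAlignment(
      set_a, set_b[[j]], type = "local",
      substitutionMatrix = blosum62(), gapOpening = gap_open,
      gapExtension = gap_ext))
  }
  m
}

oracle_rbh <- function(scores, floor = 50) {
  pairs <- list()
  for (i in seq_len(nrow(scores))) for (j in seq_len(ncol(scores))) {
    s <- scores[i, j]
    if (s < floor) next
    if (sum(scores[i, ] >= s) > 1L) next   # not the unique max of row i
    if (sum(scores[, j] >= s) > 1L) next   # not the unique max of col j
    pairs[[length(pairs) + 1L]] <- data.frame(
      gene_a = rownames(scores)[i], gene_b = colnames(scores)[j],
      score = s, stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, pairs)
}

# ---- annotation comparison -------------------------------------------------

oracle_compare <- function(ref_df, new_df, f) {
  nr <- nrow(ref_df); nn <- nrow(new_df)
  match_mat <- matrix(FALSE, nr, nn)
  for (i in seq_len(nr)) for (j in seq_len(nn)) {
    if (ref_df$chrom[i] != new_df$chrom[j]) next
    if (ref_df$strand[i] != new_df$strand[j]) next
    inter <- min(ref_df$end[i], new_df$end[j]) -
      max(ref_df$start[i], new_df$start[j]) + 1L
    if (inter <= 0L) next
    w <- ref_df$end[i] - ref_df$start[i] + 1L
    if (inter >= f * w - 1e-9) match_mat[i, j] <- TRUE
  }
  ref_deg <- rowSums(match_mat); new_deg <- colSums(match_mat)
  reciprocal <- 0L; join <- 0L
  for (i in seq_len(nr)) {
    if (ref_deg[i] != 1L) next
    j <- which(match_mat[i, ])
    if (new_deg[j] == 1L) reciprocal <- reciprocal + 1L else join <- join + 1L
  }
  list(only_ref = sum(ref_deg == 0L), only_new = sum(new_deg == 0L),
       overlap_reciprocal = reciprocal, overlap_split = sum(ref_deg >= 2L),
       overlap_join = join)
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

# ---- coding effects --------------------------------------------------------

# chromosome-level re-translation oracle: apply the variant to the raw
# chromosome string, lift the gene's CDS intervals across the single edit,
# re-splice and translate, then compare proteins
oracle_effect <- function(genome, call, gene_id) {
  f <- genome$features
  cds <- f[f$type == "CDS" & f$gene_id == gene_id]
  o <- order(BiocGenerics::start(cds)); cds <- cds[o]
  strand <- as.character(BiocGenerics::strand(cds))[1]
  chrom <- as.character(GenomeInfoDb::seqnames(cds))[1]
  refchr <- as.character(genome$seqs[[chrom]])
  delta <- nchar(call$alt) - nchar(call$ref)
  mutchr <- oracle_apply_chrom(refchr, call)
  shift <- function(p) {
    # position after the single edit
    if (nchar(call$ref) == 0L) {             # insertion before call$pos
      if (p >= call$pos) p + delta else p
    } else {
      ref_end <- call$pos + nchar(call$ref) - 1L
      if (p > ref_end) p + delta
      else if (p >= call$pos) NA_integer_    # inside the replaced span
      else p
    }
  }
  starts <- BiocGenerics::start(cds); ends <- BiocGenerics::end(cds)
  ns <- vapply(starts, shift, integer(1)); ne <- vapply(ends, shift, integer(1))
  splice_tr <- function(chr, ss, ee) {
    parts <- substring(chr, ss, ee)
    if (strand == "-")
      parts <- rev(vapply(parts, function(p) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(p))), ""))
    seq <- paste(parts, collapse = "")
    n <- nchar(seq) - nchar(seq) %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                       if.fuzzy.codon = "solve"))
  }
  ref_prot <- splice_tr(refchr, starts, ends)
  # grow/shrink the affected CDS interval with the edit it contains
  v_end <- if (nchar(call$ref) == 0L) call$pos - 1L
           else call$pos + nchar(call$ref) - 1L
  ms <- starts; me <- ends
  for (k in seq_along(starts)) {
    inside <- call$pos > starts[k] & v_end <= ends[k] |
      (nchar(call$ref) == 0L && call$pos > starts[k] && call$pos <= ends[k])
    if (inside) me[k] <- me[k] + delta
    if (!inside) {
      s2 <- shift(starts[k]); e2 <- shift(ends[k])
      if (is.na(s2) || is.na(e2)) return(NA_character_)  # exon edge destroyed
      ms[k] <- s2; me[k] <- e2
      next
    }
    ms[k] <- shift(starts[k])
    if (k < length(starts)) for (k2 in (k + 1L):length(starts)) {
      ms[k2] <- starts[k2] + delta; me[k2] <- ends[k2] + delta
    }
    break
  }
  mut_prot <- splice_tr(mutchr, ms, me)
  ref_len <- sum(ends - starts + 1L)
  mut_len <- ref_len + (if (nchar(call$ref) == 0L) delta else {
    ov <- sum(pmax(0L, pmin(ends, v_end) - pmax(starts, call$pos) + 1L))
    if (ov > 0L && ov == nchar(call$ref)) delta else -ov
  })
  if (mut_len %% 3L != 0L) return("FRAME_SHIFT")
  strip <- function(x) sub("\\*.*$", "", x)
  first_stop <- function(x) regexpr("*", x, fixed = TRUE)
  fs_m <- first_stop(mut_prot)
  if (fs_m > 0L && fs_m < nchar(mut_prot)) return("STOP_GAINED")
  if (substr(mut_prot, nchar(mut_prot), nchar(mut_prot)) != "*")
    return("STOP_LOST")
  if (substr(mut_prot, 1, 1) != "M") return("START_LOST")
  "NONE"
}

# ---- random call sets ------------------------------------------------------

random_caller_pair <- function(n_a, n_b, caller_b = "path_divergence",
                               chrom_pool = c("chr1", "chr2"),
                               pos_max = 5000L) {
  mk <- function(n, caller) {
    if (n == 0L) return(variant_calls())
    pos <- sample.int(pos_max, n)
    len <- sample(1:6, n, replace = TRUE)
    is_snp <- runif(n) < 0.6
    ref <- ifelse(is_snp, sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  vapply(len, function(l)
                    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                          collapse = ""), ""))
    alt <- ifelse(is_snp, "T", "")
    span <- pmax(nchar(ref), nchar(alt))
    variant_calls(chrom = sample(chrom_pool, n, replace = TRUE), pos = pos,
                  ref = ref, alt = alt,
                  contig_length = span + sample(5:40, n, replace = TRUE),
                  flank_quality = sample(0:60, n, replace = TRUE),
                  caller = caller)
  }
  list(a = mk(n_a, "bubble"), b = mk(n_b, caller_b))
}

rand_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

mutate_protein_chr_acc <- function(p, k) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(p, "")[[1]]
  idx <- sample(length(ch), min(k, length(ch)))
  for (i in idx) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}
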