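#' Classify genes into common, dispensable and unique sets
#'
#' Given the three pairwise positional-ortholog tables over genomes A, B and
#' C, a gene of A is `common` when it has positional orthologs in both B and
#' C (present in all three genomes), `unique` when it has none in either,
#' and `dispensable` otherwise; analogously for B and C.
#'
#' @param ortho_ab,ortho_ac,ortho_bc Pairwise ortholog tables
#'   ([positional_orthologs()]); `gene_a`/`gene_b` columns refer to the
#'   first/second genome of each pair.
#' @param genes_a,genes_b,genes_c Character vectors of gene ids (or
#'   `annotated_genome` objects) for the three genomes.
#' @param genome_names Names of the three genomes (A, B, C order).
#' @return A data.frame of class `pan_gene_classes` with `genome`,
#'   `gene_id`, `class`.
#' @export
classify_pangenes <- function(ortho_ab, ortho_ac, ortho_bc,
                              genes_a, genes_b, genes_c,
                              genome_names = c("A", "B", "C")) {
  ids <- function(x) if (inherits(x, "annotated_genome"))
    gene_table(x)$gene_id else as.character(x)
  ga <- ids(genes_a); gb <- ids(genes_b); gc_ <- ids(genes_c)
  check <- function(tab_genes, universe, label) {
    bad <- setdiff(tab_genes, universe)
    if (length(bad))
      stop("consistency error: ortholog table names gene(s) absent from ",
           label, ": ", paste(utils::head(bad, 3L), collapse = ", "))
  }
  check(ortho_ab$gene_a, ga, genome_names[1])
  check(ortho_ac$gene_a, ga, genome_names[1])
  check(ortho_ab$gene_b, gb, genome_names[2])
  check(ortho_bc$gene_a, gb, genome_names[2])
  check(ortho_ac$gene_b, gc_, genome_names[3])
  check(ortho_bc$gene_b, gc_, genome_names[3])
  cls <- function(in1, in2) ifelse(in1 & in2, "common",
                            ifelse(!in1 & !in2, "unique", "dispensable"))
  out <- rbind(
    data.frame(genome = genome_names[1], gene_id = ga,
               class = cls(ga %in% ortho_ab$gene_a, ga %in% ortho_ac$gene_a)),
    data.frame(genome = genome_names[2], gene_id = gb,
               class = cls(gb %in% ortho_ab$gene_b, gb %in% ortho_bc$gene_a)),
    data.frame(genome = genome_names[3], gene_id = gc_,
               class = cls(gc_ %in% ortho_ac$gene_b, gc_ %in% ortho_bc$gene_b)))
  rownames(out) <- NULL
  class(out) <- c("pan_gene_classes", "data.frame")
  out
}

#' Call retained and lost genes from outgroup copy counts
#'
#' For an outgroup gene with ortholog copy counts `(x, y, z)` over the three
#' genomes, the gene is `retained` for a genome when that genome has more
#' copies than the other two, which must be equal (e.g. 3,2,2), and `lost`
#' when it has fewer than the two equal others (e.g. 2,3,3). Any other
#' pattern -- including three distinct counts -- is `neither` for every
#' genome, so each retained or lost call names exactly one genome.
#'
#' @param copy_counts Data.frame with `outgroup_gene`, `genome`, `count`
#'   covering all three genomes per outgroup gene.
#' @return A data.frame with `outgroup_gene`, `genome`, `status`.
#' @export
call_retained_lost <- function(copy_counts) {
  need <- c("outgroup_gene", "genome", "count")
  miss <- setdiff(need, names(copy_counts))
  if (length(miss))
    stop("copy_counts lack column(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (og in unique(copy_counts$outgroup_gene)) {
    sub <- copy_counts[copy_counts$outgroup_gene == og, , drop = FALSE]
    if (nrow(sub) != 3L)
      stop("expected counts for exactly three genomes for ", og)
    status <- rep("neither", 3L)
    for (i in 1:3) {
      others <- sub$count[-i]
      if (others[1] == others[2]) {
        if (sub$count[i] > others[1]) status[i] <- "retained"
        if (sub$count[i] < others[1]) status[i] <- "lost"
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      outgroup_gene = og, genome = sub$genome, status = status,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a pan-genome analysis
#'
#' Tallies pan-gene classes, retained/lost statuses and ortholog copy-count
#' histograms per genome, and cross-tabulates changed (dispensable + unique)
#' genes by subgenome with per-subgenome change frequencies (changed genes
#' divided by the subgenome's gene total).
#'
#' @param classes Output of [classify_pangenes()].
#' @param statuses Output of [call_retained_lost()] (optional).
#' @param copy_counts Copy-count table with `genome` and `count` (optional).
#' @param subgenomes Data.frame with `genome`, `gene_id`, `label` (optional).
#' @return A list of class `pangenome_summary` with elements
#'   `class_counts`, `retained_lost`, `copy_histogram`,
#'   `subgenome_changes`.
#' @export
summarize_pangenome <- function(classes, statuses = NULL, copy_counts = NULL,
                                subgenomes = NULL) {
  lv <- c("common", "dispensable", "unique")
  class_counts <- as.data.frame(table(
    genome = classes$genome, class = factor(classes$class, levels = lv)),
    responseName = "n", stringsAsFactors = FALSE)
  retained_lost <- NULL
  if (!is.null(statuses))
    retained_lost <- as.data.frame(table(
      genome = statuses$genome,
      status = factor(statuses$status,
                      levels = c("retained", "lost", "neither"))),
      responseName = "n", stringsAsFactors = FALSE)
  copy_histogram <- NULL
  if (!is.null(copy_counts)) {
    cc <- copy_counts
    cc$copies <- ifelse(cc$count >= 3L, "3+", as.character(cc$count))
    copy_histogram <- as.data.frame(table(
      genome = cc$genome,
      copies = factor(cc$copies, levels = c("0", "1", "2", "3+"))),
      responseName = "n", stringsAsFactors = FALSE)
  }
  subgenome_changes <- NULL
  if (!is.null(subgenomes)) {
    m <- merge(classes, subgenomes, by = c("genome", "gene_id"), all.x = TRUE)
    m$label[is.na(m$label)] <- "unassigned"
    rows <- list()
    for (gn in unique(m$genome)) {
      sub <- m[m$genome == gn, , drop = FALSE]
      for (lab in sort(unique(sub$label))) {
        tot <- sum(sub$label == lab)
        chg <- sum(sub$label == lab & sub$class != "common")
        rows[[length(rows) + 1L]] <- data.frame(
          genome = gn, subgenome = lab, changed = chg, total = tot,
          frequency = if (tot > 0L) chg / tot else 0,
          stringsAsFactors = FALSE)
      }
    }
    subgenome_changes <- do.call(rbind, rows)
  }
  structure(list(class_counts = class_counts, retained_lost = retained_lost,
                 copy_histogram = copy_histogram,
                 subgenome_changes = subgenome_changes),
            class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat("pan-genome summary\n\nGene classes:\n")
  print(stats::reshape(x$class_counts, idvar = "genome",
                       timevar = "class", direction = "wide"),
        row.names = FALSE)
  if (!is.null(x$retained_lost)) {
    cat("\nRetained / lost (vs outgroup copy counts):\n")
    print(stats::reshape(x$retained_lost, idvar = "genome",
                         timevar = "status", direction = "wide"),
          row.names = FALSE)
  }
  if (!is.null(x$copy_histogram)) {
    cat("\nOrtholog copy-count histogram:\n")
    print(stats::reshape(x$copy_histogram, idvar = "genome",
                         timevar = "copies", direction = "wide"),
          row.names = FALSE)
  }
  if (!is.null(x$subgenome_changes)) {
    cat("\nChanged genes by subgenome:\n")
    print(x$subgenome_changes, row.names = FALSE)
  }
  invisible(x)
}
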