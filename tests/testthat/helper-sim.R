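# small simulation shared across test files (built once per session)
.sim_cache <- new.env(parent = emptyenv())

tiny_config <- function(seed = 42L, ...) {
  simulation_config(n_chromosomes = 1L, chromosome_length = 60000L,
                    n_genes_per_subgenome = 8L, seed = seed, ...)
}

cached_sim <- function(key = "default", maker = function() {
  simulate_pangenome(tiny_config())
}) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

noise_free_config <- function(seed = 1L, n_genes_per_subgenome = 8L,
                              chromosome_length = 20000L,
                              n_chromosomes = 3L, ...) {
  simulation_config(n_chromosomes = n_chromosomes,
                    chromosome_length = chromosome_length,
                    n_genes_per_subgenome = n_genes_per_subgenome,
                    snp_rate = 0, indel_rate = 0, caller_miss_prob = 0,
                    low_quality_prob = 0, seed = seed, ...)
}

truth_calls <- function(sim, genotype) {
  tv <- sim$truth$variants[[genotype]]
  variant_calls(tv$chrom, tv$pos, tv$ref, tv$alt,
                contig_length = pmax(nchar(tv$ref), nchar(tv$alt), 1L),
                flank_quality = 60L, caller = "bubble")
}

# build the three genotype-pair positional-ortholog tables of a simulation
sim_orthology <- function(sim) {
  genomes <- c(list(sim$reference), unname(sim$genotypes))
  names(genomes) <- c(sim$config$reference_name, names(sim$genotypes))
  prots <- lapply(genomes, extract_proteins)
  list(genomes = genomes, proteomes = prots,
       ab = positional_orthologs(genomes[[1]], genomes[[2]],
                                 proteome_a = prots[[1]],
                                 proteome_b = prots[[2]]),
       ac = positional_orthologs(genomes[[1]], genomes[[3]],
                                 proteome_a = prots[[1]],
                                 proteome_b = prots[[3]]),
       bc = positional_orthologs(genomes[[2]], genomes[[3]],
                                 proteome_a = prots[[2]],
                                 proteome_b = prots[[3]]))
}

sim_copy_counts <- function(sim, proteomes = NULL) {
  genomes <- c(list(sim$reference), unname(sim$genotypes))
  names(genomes) <- c(sim$config$reference_name, names(sim$genotypes))
  if (is.null(proteomes)) proteomes <- lapply(genomes, extract_proteins)
  rows <- list()
  for (og in names(sim$outgroups))
    for (gn in names(genomes)) {
      cc <- ortholog_copy_counts(sim$outgroups[[og]], proteomes[[gn]])
      cc$genome <- gn; cc$outgroup <- og
      rows[[length(rows) + 1L]] <- cc
    }
  do.call(rbind, rows)
}
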