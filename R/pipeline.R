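#' Fold-coverage estimate
#'
#' `n_reads * mean_len / genome_size`; e.g. 8e8 reads of mean length 90 over
#' a 1.2 Gb genome give ~60x.
#'
#' @param n_reads number of (quality-filtered) reads.
#' @param mean_len mean read length in bases.
#' @param genome_size haploid genome size in bases.
#' @return fold coverage.
#' @export
coverage_estimate <- function(n_reads, mean_len, genome_size) {
  if (any(c(n_reads, mean_len, genome_size) <= 0))
    stop("all coverage inputs must be positive")
  n_reads * mean_len / genome_size
}

#' Run the full simulated parentage pipeline
#'
#' Composes every stage in order: simulate parent genomes, construct the
#' hybrid, simulate reads, quality-filter, build the nuclear and
#' mitochondrial fragment databases, run both best-hit censuses, optionally
#' simulate and census a gene-tree forest, and emit the parentage call.
#' Rerunning with the same configuration reproduces the same call and, when
#' `outdir` is given, byte-identical artifacts (FASTA, FASTQ, Newick, TSV,
#' JSON plus a resolved-config copy).
#'
#' @param config a [sim_config()].
#' @param params an [alignment_params()].
#' @param forest_spec optional [gene_tree_forest_spec()]; its focal tip is
#'   taken as the hybrid and its mixture should put weight on the parents.
#' @param n_per_species fragments per species in the nuclear database
#'   (`Inf` keeps every fragment; desk-scale genomes are already balanced).
#' @param outdir optional directory for artifacts; NULL keeps everything in
#'   memory.
#' @param qc_min_phred quality-trim threshold. The simulator writes constant
#'   qualities truthfully encoding `error_rate`, so a threshold above that
#'   quality would trim every base; the default caps the usual 30 at the
#'   simulated base quality.
#' @param dam_threshold,alpha passed to [parentage_call()].
#' @param downsample effective-count cap for the F1/BC1 binomial tests.
#'   Read counts vastly overstate the number of independent ancestry draws:
#'   linked sites travel on shared parental segments, so the information
#'   about the genome-wide ancestry proportion saturates at roughly the
#'   number of independently segregating segments, not the number of reads.
#'   The default (100) matches the ancestry-proportion variance implied by
#'   the default karyotype; set NULL to test at full read counts.
#' @return the `parentage_call`, with the intermediate objects attached as
#'   attribute `artifacts`.
#' @export
run_pipeline <- function(config, params = alignment_params(),
                         forest_spec = NULL, n_per_species = Inf,
                         outdir = NULL, qc_min_phred = NULL,
                         dam_threshold = 0.99, alpha = 0.001,
                         downsample = 100L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(qc_min_phred))
    qc_min_phred <- min(30L, utf8ToInt(phred_char(config$error_rate)) - 33L)
  genomes <- simulate_parent_genomes(config)
  hybrid <- make_hybrid(genomes, config)
  reads <- simulate_reads(hybrid, config)
  reads_qc <- quality_filter(reads, min_phred = qc_min_phred)
  nuc_db <- build_fragment_db(genomes, fragment_length = 100L,
                              n_per_species = n_per_species,
                              seed = config$seed + 10L, k = 11L,
                              what = "nuclear")
  mito_db <- build_fragment_db(genomes, fragment_length = 100L,
                               n_per_species = Inf,
                               seed = config$seed + 11L, k = 11L,
                               what = "mito")
  nuclear <- hit_census(reads_qc, nuc_db, params)
  mito <- mito_census(reads_qc, mito_db, params)
  trees <- NULL
  forest <- NULL
  if (!is.null(forest_spec)) {
    forest <- simulate_gene_trees(forest_spec)
    trees <- sister_census(forest, forest_spec$focal, forest_spec$outgroup)
  }
  call <- parentage_call(nuclear, mito, trees, alpha = alpha,
                         dam_threshold = dam_threshold, downsample = downsample)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genomes_fasta(genomes, file.path(outdir, "genomes"))
    write_reads_fastq(reads, file.path(outdir, "reads.fastq"))
    write_fragment_db(nuc_db, file.path(outdir, "nuclear_db"))
    write_fragment_db(mito_db, file.path(outdir, "mito_db"))
    write_census_tsv(nuclear, file.path(outdir, "nuclear_census.tsv"))
    write_census_tsv(mito, file.path(outdir, "mito_census.tsv"))
    if (!is.null(forest)) {
      write_newick_forest(forest, file.path(outdir, "forest.nwk"))
      write_census_tsv(trees, file.path(outdir, "tree_census.tsv"))
    }
    write_report(call, file.path(outdir, "parentage_call.json"))
    cfg <- config
    cfg$species <- as.list(as.data.frame(cfg$species))
    jsonlite::write_json(unclass(cfg), file.path(outdir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  attr(call, "artifacts") <- list(genomes = genomes, hybrid = hybrid,
                                  reads = reads_qc, nuclear_db = nuc_db,
                                  mito_db = mito_db, forest = forest)
  call
}
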