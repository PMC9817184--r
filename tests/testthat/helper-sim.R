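# Small shared simulation setups; everything is generated in code at test time.

# a fast two-chromosome config for unit tests
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, genome_length = rep(2000L, 2L), mito_length = 1200L,
               read_length = 80L, n_reads = 500L, error_rate = 0.005,
               mito_read_fraction = 0)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# fraction of nuclear reads whose (majority) true origin is `species`
true_origin_share <- function(reads, species, parents) {
  nuc <- reads$origin_kind == "nuclear" & reads$origin_species %in% parents
  mean(reads$origin_species[nuc] == species)
}

# uniform random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# per-site mismatch fraction between two equal-length strings
seq_diff <- function(a, b) {
  mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
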