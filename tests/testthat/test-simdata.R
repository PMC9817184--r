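test_that("JC69 branch-length zero and saturation limits hold", {
  cfg <- sim_config(seed = 3, genome_length = 20000L, mito_length = 2000L,
                    species = data.frame(name = c("X", "Y", "Z"),
                                         divergence = c(0, 10, 0.1)),
                    parents = c("X", "Y"))
  g <- simulate_parent_genomes(cfg)
  # d = 0: identical to the ancestor
  expect_identical(g$species$X$nuclear, g$ancestor$nuclear)
  expect_identical(g$species$X$mito, g$ancestor$mito)
  # d large: ~75% of sites differ (3 SE of binomial at p = 0.75)
  d_sat <- seq_diff(g$species$Y$nuclear[[1]], g$ancestor$nuclear[[1]])
  se <- sqrt(0.75 * 0.25 / 20000)
  expect_lt(abs(d_sat - 0.75), 3 * se)
})

test_that("observed divergence matches the JC69 expectation at 1 Mb", {
  # single branch d = 0.10 against the closed-form p = 3/4 (1 - exp(-0.4/3))
  cfg <- sim_config(seed = 5, genome_length = 1000000L, mito_length = 2000L,
                    species = data.frame(name = c("P", "Q"),
                                         divergence = c(0.10, 0.05)),
                    parents = c("P", "Q"))
  g <- simulate_parent_genomes(cfg)
  p_exp <- jc69_expected_diff(0.10)
  expect_lt(abs(p_exp - 0.0935), 2e-4)
  obs <- seq_diff(g$species$P$nuclear[[1]], g$ancestor$nuclear[[1]])
  se <- sqrt(p_exp * (1 - p_exp) / 1e6)
  expect_lt(abs(obs - p_exp), 3 * se)
  # pairwise species divergence matches the d1 + d2 expectation
  p_pair <- jc69_expected_diff(0.15)
  obs_pair <- seq_diff(g$species$P$nuclear[[1]], g$species$Q$nuclear[[1]])
  expect_lt(abs(obs_pair - p_pair), 3 * sqrt(p_pair * (1 - p_pair) / 1e6))
})

test_that("genome simulation is deterministic under a fixed seed and validates input", {
  cfg <- tiny_config(seed = 9)
  expect_identical(simulate_parent_genomes(cfg), simulate_parent_genomes(cfg))
  expect_error(sim_config(genome_length = 0L), "genome_length")
  expect_error(sim_config(error_rate = 1), "error_rate")
  expect_error(sim_config(hybrid_cross = "BC1"), "backcross_parent")
  expect_error(sim_config(dam = "C"), "dam")
})

test_that("F1 hybrids carry one full haplotype per parent and the dam's mito", {
  cfg <- tiny_config(seed = 2)
  g <- simulate_parent_genomes(cfg)
  h <- make_hybrid(g, cfg)
  expect_identical(h$haplotypes[[1]]$seq, g$species$A$nuclear)
  expect_identical(h$haplotypes[[2]]$seq, g$species$B$nuclear)
  expect_identical(h$mito, g$species$A$mito) # maternal inheritance, dam = A
  expect_equal(unname(ancestry_fractions(h)), c(0.5, 0.5))
})

test_that("every hybrid position is attributed to exactly one parent", {
  for (cross in list(list("F1", NULL), list("BC1", "B"))) {
    cfg <- tiny_config(seed = 4, hybrid_cross = cross[[1]],
                       backcross_parent = cross[[2]])
    h <- make_hybrid(simulate_parent_genomes(cfg), cfg)
    for (hap in h$haplotypes) {
      for (ci in seq_along(hap$seq)) {
        expect_equal(length(hap$origin[[ci]]), unname(nchar(hap$seq[ci])))
        expect_true(all(hap$origin[[ci]] %in% 1:2))
      }
    }
  }
})

test_that("BC1 ancestry of the backcrossed parent averages 0.75 over replicates", {
  fr <- vapply(1:200, function(s) {
    cfg <- tiny_config(seed = 1000 + s, hybrid_cross = "BC1",
                       backcross_parent = "A")
    unname(ancestry_fractions(make_hybrid(simulate_parent_genomes(cfg), cfg))["A"])
  }, numeric(1))
  expect_true(all(fr >= 0.5), info = "full haplotype bounds BC1 ancestry below")
  # per-replicate sd ~ 0.102 with two chromosomes; 3 SE band around 0.75
  expect_lt(abs(mean(fr) - 0.75), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("error-free reads are exact substrings of their source haplotype", {
  cfg <- tiny_config(seed = 6, error_rate = 0, n_reads = 200L)
  g <- simulate_parent_genomes(cfg)
  h <- make_hybrid(g, cfg)
  r <- simulate_reads(h, cfg)
  for (i in sample.int(nrow(r), 25)) {
    src <- h$haplotypes[[r$hap[i]]]$seq[r$contig[i]]
    sub <- unname(substring(src, r$start[i], r$start[i] + cfg$read_length - 1L))
    expect_identical(
      if (r$strand[i] == "+") r$seq[i] else revcomp(r$seq[i]),
      sub)
  }
})

test_that("read errors occur at the configured per-base rate", {
  cfg <- sim_config(seed = 8, genome_length = 50000L, n_reads = 10000L,
                    read_length = 100L, error_rate = 0.01,
                    mito_read_fraction = 0)
  g <- simulate_parent_genomes(cfg)
  h <- make_hybrid(g, cfg)
  r <- simulate_reads(h, cfg)
  # compare each read to its error-free source substring
  n_mm <- 0L
  n_b <- 0L
  for (i in seq_len(nrow(r))) {
    src <- h$haplotypes[[r$hap[i]]]$seq[r$contig[i]]
    sub <- substring(src, r$start[i], r$start[i] + 99L)
    obs <- if (r$strand[i] == "+") r$seq[i] else revcomp(r$seq[i])
    n_mm <- n_mm + sum(strsplit(obs, "")[[1]] != strsplit(sub, "")[[1]])
    n_b <- n_b + 100L
  }
  se <- sqrt(0.01 * 0.99 / n_b)
  expect_lt(abs(n_mm / n_b - 0.01), 3 * se)
})

test_that("the mitochondrial read fraction is binomial around its target", {
  cfg <- sim_config(seed = 12, n_reads = 10000L, mito_read_fraction = 0.1)
  h <- make_hybrid(simulate_parent_genomes(cfg), cfg)
  r <- simulate_reads(h, cfg)
  n_mito <- sum(r$origin_kind == "mito")
  se <- sqrt(0.1 * 0.9 * 10000)
  expect_lt(abs(n_mito - 1000), 3 * se)
  expect_true(all(r$origin_species[r$origin_kind == "mito"] == "A"))
  expect_error(simulate_reads(h, sim_config(n_reads = 0L)), "n_reads")
})

test_that("gene-tree forests realize pure, quota and Bernoulli sister mixtures", {
  taxa <- c("hyb", "A", "B", "C", "D", "out")
  # pure mixture: every tree has A as the focal sister
  sp1 <- gene_tree_forest_spec(50, taxa, "hyb", "out",
                               sister_mixture = c(A = 1), seed = 3)
  f1 <- simulate_gene_trees(sp1)
  cen1 <- sister_census(f1, "hyb", "out")
  expect_equal(unname(cen1$counts["A"]), 50L)
  expect_equal(cen1$n_multi_sister, 0L)

  # quota sampling reproduces an exact category table
  q <- c(A = 30L, B = 15L, C = 5L, multi = 10L)
  sp2 <- gene_tree_forest_spec(60, taxa, "hyb", "out", method = "quota",
                               quota = q, seed = 4)
  f2 <- simulate_gene_trees(sp2)
  cen2 <- sister_census(f2, "hyb", "out")
  expect_equal(cen2$counts[c("A", "B", "C")], q[c("A", "B", "C")])
  expect_equal(cen2$n_multi_sister, 10L)
  expect_equal(cen2$n_singleton, 50L)

  # Bernoulli sampling recovers the mixture within 3 binomial SE
  mix <- c(A = 0.45, B = 0.34, C = 0.11)
  sp3 <- gene_tree_forest_spec(4000, taxa, "hyb", "out", sister_mixture = mix,
                               non_singleton_fraction = 0.10, seed = 5)
  cen3 <- sister_census(simulate_gene_trees(sp3), "hyb", "out")
  for (s in names(mix)) {
    obs <- cen3$counts[s] / 4000
    expect_lt(abs(obs - mix[s]), 3 * sqrt(mix[s] * (1 - mix[s]) / 4000))
  }
  expect_error(
    gene_tree_forest_spec(10, taxa, "hyb", "out",
                          sister_mixture = c(A = 0.5), non_singleton_fraction = 0),
    "sum to 1")
})

test_that("simulation outputs are byte-identical across reruns of one config", {
  cfg <- tiny_config(seed = 31, mito_read_fraction = 0.1)
  r1 <- simulate_reads(make_hybrid(simulate_parent_genomes(cfg), cfg), cfg)
  r2 <- simulate_reads(make_hybrid(simulate_parent_genomes(cfg), cfg), cfg)
  expect_identical(r1, r2)
  sp <- gene_tree_forest_spec(20, c("h", "A", "B", "o"), "h", "o",
                              sister_mixture = c(A = 0.6, B = 0.4), seed = 7)
  expect_identical(simulate_gene_trees(sp), simulate_gene_trees(sp))
})
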