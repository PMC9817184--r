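mk_reads <- function(seqs, quals) {
  data.frame(id = paste0("r", seq_along(seqs)), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

test_that("quality filtering trims 3' tails and drops short or masked reads", {
  q30 <- intToUtf8(30 + 33)
  q10 <- intToUtf8(10 + 33)
  reads <- mk_reads(
    c(strrep("ACGT", 25),                          # clean 100-mer
      paste0(strrep("AC", 20), strrep("G", 10)),   # 50 bases, low-quality tail of 10
      strrep("A", 40),                             # trims to 29 -> dropped
      paste0(strrep("N", 31), strrep("ACGT", 25))),# 31 masked bases -> dropped
    c(strrep(q30, 100),
      paste0(strrep(q30, 40), strrep(q10, 10)),
      paste0(strrep(q30, 29), strrep(q10, 11)),
      strrep(q30, 131)))
  out <- quality_filter(reads, min_phred = 30, min_len = 30, max_masked = 30)
  expect_equal(out$id, c("r1", "r2"))
  expect_equal(out$seq[1], strrep("ACGT", 25))           # untouched
  expect_equal(nchar(out$seq[2]), 40L)                   # tail trimmed
  expect_equal(attr(out, "n_dropped_short"), 1L)
  expect_equal(attr(out, "n_dropped_masked"), 1L)
  # malformed record is named
  bad <- mk_reads("ACGT", strrep(q30, 3))
  expect_error(quality_filter(bad), "r1")
})

test_that("a read with exactly 30 masked bases survives, 31 does not", {
  q <- strrep(intToUtf8(35 + 33), 100)
  borderline <- mk_reads(c(paste0(strrep("N", 30), strrep("A", 70)),
                           paste0(strrep("N", 31), strrep("A", 69))),
                         c(q, q))
  out <- quality_filter(borderline)
  expect_equal(out$id, "r1")
})

aln_row <- function(read_idx, species, score, frag = paste0(species, "|c|0"),
                    m = 100, n = 4e5, params = alignment_params()) {
  data.frame(read_idx = read_idx, read_id = paste0("r", read_idx),
             fragment_id = frag, species = species, strand = "+",
             score = score, bitscore = bit_score(score, params),
             evalue = karlin_altschul_evalue(score, m, n, params),
             stringsAsFactors = FALSE)
}

test_that("the best-hit rule assigns, discards cross-species ties, and keeps same-species ties", {
  # clear winner
  a <- rbind(aln_row(1, "A", 90), aln_row(1, "B", 80))
  expect_equal(best_hit(a)$outcome, "assigned")
  expect_equal(best_hit(a)$species, "A")
  # two species at the same minimal E -> discard
  b <- rbind(aln_row(1, "A", 90), aln_row(1, "B", 90))
  hb <- best_hit(b)
  expect_equal(hb$outcome, "tie_discarded")
  expect_equal(hb$species, c("A", "B"))
  # two fragments of the same species tied, another species worse -> assigned
  c3 <- rbind(aln_row(1, "A", 90, frag = "A|c|0"),
              aln_row(1, "A", 90, frag = "A|c|100"),
              aln_row(1, "B", 70))
  hc <- best_hit(c3)
  expect_equal(hc$outcome, "assigned")
  expect_equal(hc$species, "A")
  # nothing at all -> no hit
  expect_equal(best_hit(NULL)$outcome, "no_hit")
})

test_that("batch assignment matches the per-read rule and conserves queries", {
  reads <- mk_reads(rep("ACGT", 4), rep("!!!!", 4))
  aln <- rbind(aln_row(1, "A", 90), aln_row(1, "B", 80),
               aln_row(2, "A", 85), aln_row(2, "B", 85),
               aln_row(3, "B", 60))
  asg <- assign_best_hits(aln, reads)
  expect_equal(asg$outcome, c("assigned", "tie_discarded", "assigned", "no_hit"))
  expect_equal(asg$species[c(1, 3)], c("A", "B"))
  expect_equal(asg$tie_species[2], "A,B")
  cen <- census(asg)
  expect_equal(cen$n_assigned + cen$n_tie_discarded + cen$n_no_hit, cen$n_total)
  expect_equal(sum(cen$proportions), 1)
  expect_equal(unname(cen$counts[c("A", "B")]), c(1L, 1L))
})

test_that("the census is order-invariant and relabeling-equivariant", {
  reads <- mk_reads(rep("ACGT", 6), rep("!!!!", 6))
  aln <- do.call(rbind, lapply(1:6, function(i)
    aln_row(i, c("A", "A", "B", "A", "C", "B")[i], 50 + i)))
  cen <- census(assign_best_hits(aln, reads))
  perm <- sample(nrow(aln))
  cen_p <- census(assign_best_hits(aln[perm, ], reads))
  expect_equal(cen$counts, cen_p$counts)
  # relabel species A<->B everywhere: proportions permute identically
  aln2 <- aln
  aln2$species <- c(A = "B", B = "A", C = "C")[aln$species]
  cen2 <- census(assign_best_hits(aln2, reads))
  expect_equal(unname(cen2$proportions[c("B", "A", "C")]),
               unname(cen$proportions[c("A", "B", "C")]))
})

test_that("an all-one-species alignment set yields proportion one", {
  reads <- mk_reads(rep("ACGT", 3), rep("!!!!", 3))
  aln <- rbind(aln_row(1, "A", 50), aln_row(2, "A", 60), aln_row(3, "A", 70))
  cen <- census(assign_best_hits(aln, reads))
  expect_equal(unname(cen$proportions["A"]), 1)
})

test_that("mito census separates dam reads from nuclear background", {
  cfg <- sim_config(seed = 44, genome_length = rep(5000L, 2L),
                    mito_length = 4000L, n_reads = 4000L,
                    read_length = 100L, error_rate = 0.01,
                    mito_read_fraction = 0.5)
  g <- simulate_parent_genomes(cfg)
  h <- make_hybrid(g, cfg)
  r <- simulate_reads(h, cfg)
  mdb <- build_fragment_db(g, what = "mito")
  mc <- mito_census(r, mdb)
  # the dam dominates mito-assigned reads
  expect_equal(names(which.max(mc$proportions)), "A")
  expect_gte(unname(mc$proportions["A"]), 0.999)
  # nuclear reads overwhelmingly fail to hit the mito database
  n_nuclear <- sum(r$origin_kind == "nuclear")
  expect_gte(mc$n_no_hit, 0.99 * n_nuclear)
  # empty mito database errors
  mdb_empty <- mdb
  mdb_empty$fragments <- mdb$fragments[0, ]
  expect_error(mito_census(r, mdb_empty), "empty")
  # zero mito reads: defined empty census
  cfg0 <- sim_config(seed = 45, genome_length = rep(5000L, 2L),
                     mito_length = 4000L, n_reads = 50L,
                     read_length = 100L, mito_read_fraction = 0)
  g0 <- simulate_parent_genomes(cfg0)
  r0 <- simulate_reads(make_hybrid(g0, cfg0), cfg0)
  mc0 <- mito_census(r0, build_fragment_db(g0, what = "mito"))
  expect_equal(mc0$n_assigned, 0L)
})
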