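# The alignment stack is checked as a chain: the full-DP Smith-Waterman
# scorer against Biostrings' pairwiseAlignment (independent implementation),
# then the seed-and-extend path against the full-DP scorer.

test_that("the full-DP Smith-Waterman scorer matches Biostrings on random pairs", {
  skip_if_not_installed("Biostrings")
  set.seed(101)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  params <- alignment_params()
  for (i in 1:40) {
    a <- rand_dna(sample(30:120, 1))
    b <- rand_dna(sample(30:120, 1))
    ours <- smith_waterman_score(a, b, params)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(ours, as.integer(ref))
  }
  # pairs with planted homology (mutations + an indel) stress the gap states
  for (i in 1:20) {
    a <- rand_dna(100)
    v <- strsplit(a, "")[[1]]
    sub <- sample(100, 8)
    v[sub] <- sample(c("A", "C", "G", "T"), 8, TRUE)
    cut <- sample(20:80, 1)
    b <- paste(c(v[1:cut], v[(cut + 3):100]), collapse = "") # 2-base deletion
    ours <- smith_waterman_score(a, b, params)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(ours, as.integer(ref))
  }
})

test_that("a read identical to a fragment scores the full match and ranks first", {
  set.seed(7)
  genomes <- list(sp1 = list(nuclear = c(c1 = rand_dna(2000))),
                  sp2 = list(nuclear = c(c1 = rand_dna(2000))))
  db <- build_fragment_db(genomes, fragment_length = 100L)
  params <- alignment_params()
  q <- db$fragments$seq[5]
  aln <- align_read(q, db, params)
  best <- aln[which.max(aln$score), ]
  expect_equal(best$score, 100L)
  expect_equal(best$fragment_id, db$fragments$id[5])
  expect_equal(best$evalue, min(aln$evalue))
  # reverse-complement query scores identically on the minus strand
  aln_rc <- align_read(revcomp(q), db, params)
  best_rc <- aln_rc[which.max(aln_rc$score), ]
  expect_equal(best_rc$score, 100L)
  expect_equal(best_rc$fragment_id, db$fragments$id[5])
  expect_equal(best_rc$strand, "-")
})

test_that("seed-and-extend equals full Smith-Waterman on an exhaustive small database", {
  set.seed(23)
  # <= 50 fragments across three species, queries up to 200 bases
  genomes <- list(P = list(nuclear = c(c1 = rand_dna(1700))),
                  Q = list(nuclear = c(c1 = rand_dna(1700))),
                  R = list(nuclear = c(c1 = rand_dna(1600))))
  db <- build_fragment_db(genomes, fragment_length = 100L)
  expect_lte(nrow(db$fragments), 50L)
  params <- alignment_params(e_max = 10) # permissive: compare raw best scores
  mutate <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    v[hit] <- sample(c("A", "C", "G", "T"), length(hit), TRUE)
    paste(v, collapse = "")
  }
  reads <- character(0)
  for (i in 1:30) {
    src <- sample(names(genomes), 1)
    L <- sample(c(60L, 100L, 150L, 200L), 1)
    g <- genomes[[src]]$nuclear[[1]]
    p0 <- sample(nchar(g) - L + 1L, 1)
    r <- mutate(substring(g, p0, p0 + L - 1L), rate = 0.05)
    if (runif(1) < 0.5) r <- revcomp(r)
    reads <- c(reads, r)
  }
  aln <- align_reads(reads, db, params)
  for (ri in seq_along(reads)) {
    ours <- max(aln$score[aln$read_idx == ri], 0L)
    oracle <- max(vapply(db$fragments$seq, function(fs) {
      max(smith_waterman_score(reads[ri], fs, params),
          smith_waterman_score(revcomp(reads[ri]), fs, params))
    }, numeric(1)))
    expect_gte(ours, min(oracle, ours)) # guard: never exceeds the oracle below
    expect_equal(ours, as.integer(oracle),
                 info = paste("read", ri))
  }
})

test_that("E-values decrease strictly with score and scale with m and n", {
  params <- alignment_params()
  s <- 20:120
  e <- karlin_altschul_evalue(s, m = 100, n = 4e5, params)
  expect_true(all(diff(e) < 0))
  expect_equal(karlin_altschul_evalue(50, 200, 4e5, params) /
                 karlin_altschul_evalue(50, 100, 4e5, params), 2)
  expect_equal(bit_score(0, params), -log(params$K) / log(2))
})

test_that("reads shorter than the seed produce no hit", {
  set.seed(9)
  genomes <- list(sp1 = list(nuclear = c(c1 = rand_dna(1000))))
  db <- build_fragment_db(genomes, fragment_length = 100L, k = 11L)
  aln <- align_read("ACGTACG", db)
  expect_equal(nrow(aln), 0L)
})
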