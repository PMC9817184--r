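#' Simulation configuration for hybrid read-census experiments
#'
#' Bundles every knob of the synthetic-data generator: candidate parent
#' species and their divergences from a shared ancestor (Jukes-Cantor branch
#' lengths, expected substitutions per site), the cross to simulate (F1 or
#' first-generation backcross), and the sequencing layer (read length, read
#' count, per-base error rate, fraction of reads drawn from the mitochondrial
#' genome).
#'
#' Species sit on a star phylogeny: each is derived independently from the
#' common ancestor by its own branch length, so the expected observed
#' divergence between two species with branches `d1` and `d2` is the
#' Jukes-Cantor transformation of `d1 + d2`.
#'
#' @param seed integer seed; all downstream simulation draws derive from it.
#' @param genome_length integer vector of nuclear chromosome (contig) lengths
#'   in bases per species. The default emulates a small multi-chromosome
#'   karyotype (10 x 10 kb): with one crossover per chromosome, independent
#'   segregation across chromosomes concentrates BC1 ancestry near its 0.75
#'   expectation, as in real karyotypes. A single value gives one contig.
#' @param mito_length mitochondrial genome length in bases.
#' @param species data.frame with columns `name`, `divergence` and optionally
#'   `mito_divergence` (defaults to `divergence`): branch lengths from the
#'   ancestor in expected substitutions/site.
#' @param hybrid_cross `"F1"` or `"BC1"` (F1 backcrossed to one parent).
#' @param parents character vector of two species names crossed to make the F1.
#' @param dam which parent is the mother (contributes the mitochondrion).
#' @param backcross_parent for BC1, the parent the F1 is crossed back to.
#' @param n_crossovers crossovers per contig when forming the recombinant BC1
#'   gamete; placed uniformly.
#' @param read_length,n_reads,error_rate sequencing layer: read length in
#'   bases, number of reads, per-base substitution error probability.
#' @param mito_read_fraction fraction of reads drawn from the mitochondrial
#'   genome rather than the nuclear haplotypes.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = rep(10000L, 10L),
                       mito_length = 16000L,
                       species = data.frame(
                         name = c("A", "B", "C", "D"),
                         divergence = 0.05
                       ),
                       hybrid_cross = c("F1", "BC1"),
                       parents = species$name[1:2],
                       dam = parents[1],
                       backcross_parent = NULL,
                       n_crossovers = 1L,
                       read_length = 100L,
                       n_reads = 20000L,
                       error_rate = 0.005,
                       mito_read_fraction = 0.05) {
  hybrid_cross <- match.arg(hybrid_cross)
  stopifnot(is.data.frame(species), all(c("name", "divergence") %in% names(species)))
  if (is.null(species$mito_divergence)) species$mito_divergence <- species$divergence
  if (any(genome_length <= 0)) stop("genome_length must be positive")
  if (mito_length <= 0) stop("mito_length must be positive")
  if (any(species$divergence < 0) || any(species$mito_divergence < 0))
    stop("divergences must be >= 0")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (read_length > min(genome_length)) stop("read_length exceeds shortest contig")
  if (read_length > mito_length && mito_read_fraction > 0)
    stop("read_length exceeds mito_length")
  if (anyDuplicated(species$name)) stop("duplicate species names")
  if (!all(parents %in% species$name) || length(parents) != 2)
    stop("parents must name two species in `species`")
  if (!dam %in% parents) stop("dam must be one of the two parents")
  if (hybrid_cross == "BC1") {
    if (is.null(backcross_parent)) stop("BC1 requires backcross_parent")
    if (!backcross_parent %in% parents)
      stop("backcross_parent must be one of the two parents")
  }
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    mito_length = as.integer(mito_length), species = species,
    hybrid_cross = hybrid_cross, parents = parents, dam = dam,
    backcross_parent = backcross_parent, n_crossovers = as.integer(n_crossovers),
    read_length = as.integer(read_length), n_reads = as.integer(n_reads),
    error_rate = error_rate, mito_read_fraction = mito_read_fraction
  ), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_seq_codes <- function(n) sample.int(4L, n, replace = TRUE)

codes_to_string <- function(codes) paste(BASES[codes], collapse = "")

string_to_codes <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], BASES)
}

# Evolve integer-coded sequence along a JC69 branch of length d: each site
# differs from the ancestor with probability p = 3/4 (1 - exp(-4d/3)) and,
# given a difference, is uniform over the three other bases.
jc69_mutate <- function(codes, d) {
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(runif(length(codes)) < p)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
  }
  codes
}

#' Expected observed divergence under Jukes-Cantor
#'
#' `p = 3/4 (1 - exp(-4d/3))` for total branch length `d`.
#'
#' @param d branch length in expected substitutions per site.
#' @return expected fraction of differing sites.
#' @export
jc69_expected_diff <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Simulate candidate parent genomes on a star phylogeny
#'
#' Draws a uniform-random ancestor (nuclear contigs plus a mitochondrial
#' genome) and derives each species by Jukes-Cantor substitution along its own
#' branch. Deterministic for a fixed config.
#'
#' @param config a [sim_config()].
#' @return a `genome_set`: per species a list with `nuclear` (named character
#'   vector of contigs) and `mito` (single sequence), plus provenance metadata.
#' @export
simulate_parent_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    anc_nuc <- lapply(config$genome_length, random_seq_codes)
    names(anc_nuc) <- paste0("contig", seq_along(anc_nuc))
    anc_mito <- random_seq_codes(config$mito_length)
    species <- vector("list", nrow(config$species))
    names(species) <- config$species$name
    for (i in seq_len(nrow(config$species))) {
      d <- config$species$divergence[i]
      dm <- config$species$mito_divergence[i]
      nuc <- vapply(anc_nuc, function(a) codes_to_string(jc69_mutate(a, d)), "")
      species[[i]] <- list(nuclear = nuc, mito = codes_to_string(jc69_mutate(anc_mito, dm)))
    }
    structure(list(
      species = species,
      ancestor = list(
        nuclear = vapply(anc_nuc, codes_to_string, ""),
        mito = codes_to_string(anc_mito)
      ),
      meta = list(seed = config$seed, divergence = config$species)
    ), class = "genome_set")
  })
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x$species), "species\n")
  for (nm in names(x$species)) {
    sp <- x$species[[nm]]
    cat(sprintf("  %s: %d nuclear contig(s), %s nuclear bp, mito %s bp\n", nm,
                length(sp$nuclear), format(sum(nchar(sp$nuclear)), big.mark = ","),
                format(nchar(sp$mito), big.mark = ",")))
  }
  invisible(x)
}

#' Construct an F1 or BC1 hybrid genome
#'
#' An F1 carries one full haplotype from each parent. A BC1 carries one full
#' haplotype from the backcrossed parent plus one recombinant haplotype drawn
#' from the F1's two haplotypes through `n_crossovers` uniformly placed
#' crossovers per contig, so the expected ancestry fraction of the backcrossed
#' parent is 0.75. The mitochondrion is copied verbatim from the dam. A
#' per-base true-origin track records which parent contributed every position.
#'
#' @param genomes a `genome_set` containing both parents.
#' @param config a [sim_config()].
#' @return a `hybrid_genome`: two haplotypes (each `seq` + integer `origin`
#'   track, 1 = first parent, 2 = second), `mito`, and cross metadata.
#' @export
make_hybrid <- function(genomes, config) {
  stopifnot(inherits(genomes, "genome_set"), inherits(config, "sim_config"))
  p <- config$parents
  if (!all(p %in% names(genomes$species))) stop("parents not present in genome_set")
  g1 <- genomes$species[[p[1]]]
  g2 <- genomes$species[[p[2]]]
  full_hap <- function(g, idx) {
    list(seq = g$nuclear,
         origin = lapply(nchar(g$nuclear), function(L) rep.int(idx, L)))
  }
  with_seed(config$seed + 2L, {
    if (config$hybrid_cross == "F1") {
      haps <- list(full_hap(g1, 1L), full_hap(g2, 2L))
    } else {
      bp <- config$backcross_parent
      if (is.null(bp)) stop("BC1 requires backcross_parent")
      bp_idx <- match(bp, p)
      gb <- genomes$species[[bp]]
      # recombinant gamete from the F1: alternate parental segments between
      # uniformly placed crossovers
      rec_seq <- character(length(g1$nuclear))
      rec_ori <- vector("list", length(g1$nuclear))
      for (ci in seq_along(g1$nuclear)) {
        L <- nchar(g1$nuclear[ci])
        ncx <- min(config$n_crossovers, L - 1L)
        cuts <- if (ncx > 0) sort(sample.int(L - 1L, ncx)) else integer(0)
        bounds <- c(0L, cuts, L)
        cur <- sample.int(2L, 1L) # which F1 haplotype starts the gamete
        segs <- character(length(bounds) - 1L)
        ori <- integer(L)
        for (si in seq_len(length(bounds) - 1L)) {
          from <- bounds[si] + 1L
          to <- bounds[si + 1L]
          src <- if (cur == 1L) g1 else g2
          segs[si] <- substring(src$nuclear[ci], from, to)
          ori[from:to] <- cur
          cur <- 3L - cur
        }
        rec_seq[ci] <- paste(segs, collapse = "")
        rec_ori[[ci]] <- ori
      }
      names(rec_seq) <- names(g1$nuclear)
      haps <- list(full_hap(gb, bp_idx), list(seq = rec_seq, origin = rec_ori))
    }
    structure(list(
      haplotypes = haps,
      mito = genomes$species[[config$dam]]$mito,
      parents = p, dam = config$dam,
      sire = setdiff(p, config$dam),
      cross = config$hybrid_cross,
      backcross_parent = config$backcross_parent
    ), class = "hybrid_genome")
  })
}

#' Per-parent ancestry fractions of a hybrid genome
#'
#' Averages the true-origin track over both haplotypes.
#'
#' @param hybrid a `hybrid_genome`.
#' @return named numeric of length 2 summing to 1.
#' @export
ancestry_fractions <- function(hybrid) {
  stopifnot(inherits(hybrid, "hybrid_genome"))
  tot <- c(0, 0)
  n <- 0
  for (h in hybrid$haplotypes) {
    for (ori in h$origin) {
      tot[1] <- tot[1] + sum(ori == 1L)
      tot[2] <- tot[2] + sum(ori == 2L)
      n <- n + length(ori)
    }
  }
  setNames(tot / n, hybrid$parents)
}

phred_char <- function(error_rate) {
  q <- if (error_rate <= 0) 40L else min(40L, as.integer(round(-10 * log10(error_rate))))
  intToUtf8(q + 33L)
}

# apply uniform substitution errors to a character vector of fixed-width reads
apply_read_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  widths <- nchar(seqs)
  joined <- paste(seqs, collapse = "")
  codes <- string_to_codes(joined)
  hit <- which(runif(length(codes)) < error_rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
  }
  joined <- codes_to_string(codes)
  ends <- cumsum(widths)
  substring(joined, ends - widths + 1L, ends)
}

#' Simulate error-bearing short reads from a hybrid (or parent) genome
#'
#' Reads start uniformly along each source sequence, come off either strand
#' with equal probability, and carry independent per-base substitution errors.
#' A fraction `mito_read_fraction` of reads is drawn from the mitochondrial
#' genome. Each read keeps its true origin (species attribution from the
#' hybrid's origin track: the parent contributing the majority of the read's
#' span) so that downstream censuses can be scored against truth. Quality
#' strings are constant at the Phred equivalent of `error_rate`.
#'
#' @param source a `hybrid_genome`, or one species entry of a `genome_set`
#'   (a list with `nuclear` and `mito`).
#' @param config a [sim_config()].
#' @return a data.frame (`read_set`) with columns `id`, `seq`, `qual`,
#'   `origin_species`, `origin_kind` ("nuclear"/"mito"), `hap`, `contig`,
#'   `start`, `strand`.
#' @export
simulate_reads <- function(source, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reads <= 0) stop("n_reads must be positive")
  L <- config$read_length
  is_hybrid <- inherits(source, "hybrid_genome")
  if (is_hybrid) {
    contigs <- source$haplotypes[[1]]$seq
  } else {
    if (!is.list(source) || is.null(source$nuclear))
      stop("source must be a hybrid_genome or a genome_set species entry")
    contigs <- source$nuclear
  }
  if (any(nchar(contigs) < L)) stop("read_length exceeds a source contig")

  with_seed(config$seed + 3L, {
    n <- config$n_reads
    from_mito <- runif(n) < config$mito_read_fraction
    n_nuc <- sum(!from_mito)
    hap <- integer(n)
    contig <- integer(n)
    start <- integer(n)
    # nuclear reads: haplotype uniform, contig weighted by placeable starts
    hap[!from_mito] <- if (is_hybrid) sample.int(2L, n_nuc, replace = TRUE) else 1L
    weights <- pmax(nchar(contigs) - L + 1L, 0L)
    contig[!from_mito] <- sample.int(length(contigs), n_nuc, replace = TRUE,
                                     prob = weights)
    mito_seq <- source$mito
    if (any(from_mito))
      start[from_mito] <- sample.int(nchar(mito_seq) - L + 1L, sum(from_mito),
                                     replace = TRUE)
    for (ci in seq_along(contigs)) {
      sel <- !from_mito & contig == ci
      if (any(sel))
        start[sel] <- sample.int(weights[ci], sum(sel), replace = TRUE)
    }
    seqs <- character(n)
    origin <- character(n)
    for (hi in 1:2) {
      sel <- !from_mito & hap == hi
      if (!any(sel)) next
      src <- if (is_hybrid) source$haplotypes[[hi]]$seq else contigs
      for (ci in seq_along(contigs)) {
        s2 <- sel & contig == ci
        if (!any(s2)) next
        seqs[s2] <- substring(src[ci], start[s2], start[s2] + L - 1L)
        if (is_hybrid) {
          ori <- source$haplotypes[[hi]]$origin[[ci]]
          # majority parent across the read span
          cums <- c(0L, cumsum(ori == 1L))
          n1 <- cums[start[s2] + L] - cums[start[s2]]
          origin[s2] <- ifelse(n1 * 2L >= L, source$parents[1], source$parents[2])
        }
      }
    }
    if (any(from_mito)) {
      seqs[from_mito] <- substring(mito_seq, start[from_mito],
                                   start[from_mito] + L - 1L)
      if (is_hybrid) origin[from_mito] <- source$dam
    }
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- apply_read_errors(seqs, config$error_rate)
    rc <- strand == "-"
    if (any(rc)) seqs[rc] <- cpp_revcomp(seqs[rc])
    data.frame(
      id = sprintf("read%06d|%s|%s", seq_len(n),
                   ifelse(from_mito, "mito", paste0("hap", hap)),
                   if (is_hybrid) origin else ""),
      seq = seqs,
      qual = strrep(phred_char(config$error_rate), L),
      origin_species = if (is_hybrid) origin else NA_character_,
      origin_kind = ifelse(from_mito, "mito", "nuclear"),
      hap = ifelse(from_mito, NA_integer_, hap),
      contig = ifelse(from_mito, NA_integer_, contig),
      start = start,
      strand = strand,
      stringsAsFactors = FALSE
    )
  })
}

#' Specification of a simulated gene-tree forest
#'
#' Controls the focal tip's sister category across a forest: with probability
#' `sister_mixture[s]` the focal tip's sister is the single leaf `s`; with
#' probability `non_singleton_fraction` the sister is a two-leaf clade (so the
#' tree fails the singleton-sister filter). The probabilities must sum to 1.
#' In `"quota"` mode exact per-category counts are supplied instead, so a
#' forest reproduces a target census table exactly.
#'
#' @param n_trees number of trees.
#' @param taxa all leaf names, including `focal` and `outgroup`.
#' @param focal,outgroup focal (hybrid) tip and outgroup leaf names.
#' @param sister_mixture named probabilities over candidate sister species.
#' @param non_singleton_fraction probability of a multi-leaf sister clade.
#' @param seed integer seed.
#' @param method `"bernoulli"` (sample categories independently) or `"quota"`.
#' @param quota named integer counts per category (species names plus
#'   `"multi"`), required for `"quota"`; must sum to `n_trees`.
#' @return a `gene_tree_forest_spec`.
#' @export
gene_tree_forest_spec <- function(n_trees, taxa, focal, outgroup,
                                  sister_mixture = NULL,
                                  non_singleton_fraction = 0,
                                  seed = 1L,
                                  method = c("bernoulli", "quota"),
                                  quota = NULL) {
  method <- match.arg(method)
  stopifnot(n_trees > 0, focal %in% taxa, outgroup %in% taxa)
  if (method == "bernoulli") {
    if (is.null(names(sister_mixture)) || !all(names(sister_mixture) %in% taxa))
      stop("sister_mixture must be named by taxa")
    if (abs(sum(sister_mixture) + non_singleton_fraction - 1) > 1e-8)
      stop("sister_mixture plus non_singleton_fraction must sum to 1")
  } else {
    if (is.null(quota) || is.null(names(quota))) stop("quota mode needs named counts")
    if (sum(quota) != n_trees) stop("quota counts must sum to n_trees")
    if (!all(setdiff(names(quota), "multi") %in% taxa))
      stop("quota names must be taxa (plus optional 'multi')")
  }
  cats <- c(names(sister_mixture), setdiff(names(quota), "multi"))
  if (focal %in% cats || outgroup %in% cats)
    stop("focal/outgroup cannot be sister categories")
  structure(list(n_trees = as.integer(n_trees), taxa = taxa, focal = focal,
                 outgroup = outgroup, sister_mixture = sister_mixture,
                 non_singleton_fraction = non_singleton_fraction,
                 seed = as.integer(seed), method = method, quota = quota),
            class = "gene_tree_forest_spec")
}

# random fully-resolved rooted newick over a label set, branch lengths 1
random_subtree_newick <- function(labels) {
  nodes <- paste0(labels, ":1")
  while (length(nodes) > 1) {
    pick <- sample.int(length(nodes), 2L)
    joined <- paste0("(", nodes[pick[1]], ",", nodes[pick[2]], "):1")
    nodes <- c(nodes[-pick], joined)
  }
  sub(":1$", "", nodes)
}

#' Simulate a forest of gene trees with a controlled sister mixture
#'
#' Every tree contains all taxa, is rooted by construction with the outgroup
#' as one child of the root, and places the focal tip's sister according to
#' the forest specification: a single leaf drawn from `sister_mixture`, or
#' (non-singleton
#' case) a two-leaf clade. All branch lengths are 1; the census downstream is
#' topology-only.
#'
#' @param spec a [gene_tree_forest_spec()].
#' @return character vector of Newick strings; attribute `category` records
#'   each tree's drawn sister category (`"multi"` for non-singleton).
#' @export
simulate_gene_trees <- function(spec) {
  stopifnot(inherits(spec, "gene_tree_forest_spec"))
  with_seed(spec$seed, {
    if (spec$method == "quota") {
      cats <- sample(rep(names(spec$quota), times = spec$quota))
    } else {
      cats <- sample(c(names(spec$sister_mixture), "multi"), spec$n_trees,
                     replace = TRUE,
                     prob = c(spec$sister_mixture, spec$non_singleton_fraction))
    }
    pool <- setdiff(spec$taxa, c(spec$focal, spec$outgroup))
    trees <- character(spec$n_trees)
    for (i in seq_len(spec$n_trees)) {
      if (cats[i] == "multi") {
        pair <- sample(pool, 2L)
        rest <- setdiff(pool, pair)
        focal_clade <- paste0("(", spec$focal, ":1,(", pair[1], ":1,",
                              pair[2], ":1):1):1")
      } else {
        rest <- setdiff(pool, cats[i])
        focal_clade <- paste0("(", spec$focal, ":1,", cats[i], ":1):1")
      }
      inner <- if (length(rest) > 0) {
        paste0("(", focal_clade, ",", random_subtree_newick(rest), ":1):1")
      } else {
        focal_clade
      }
      trees[i] <- paste0("(", inner, ",", spec$outgroup, ":1);")
    }
    attr(trees, "category") <- cats
    trees
  })
}
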