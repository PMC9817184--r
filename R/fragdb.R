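#' Tile a genome into fixed-length fragments
#'
#' Partitions each contig into non-overlapping fragments of exactly
#' `fragment_length` bases starting at position 0; a terminal remainder
#' shorter than `fragment_length` is discarded. Fragment ids encode species,
#' contig and 0-based start (`species|contig|start`).
#'
#' @param contigs named character vector of contig sequences.
#' @param fragment_length fragment size in bases (the census design uses 100).
#' @param species species label attached to every fragment.
#' @return data.frame with columns `id`, `species`, `contig`, `start`, `seq`.
#' @export
tile_fragments <- function(contigs, fragment_length = 100L, species = "unknown") {
  if (fragment_length <= 0) stop("fragment_length must be positive")
  if (length(contigs) == 0 || all(nchar(contigs) == 0)) stop("empty genome")
  if (is.null(names(contigs))) names(contigs) <- paste0("contig", seq_along(contigs))
  out <- lapply(seq_along(contigs), function(ci) {
    L <- nchar(contigs[ci])
    nfrag <- L %/% fragment_length
    if (nfrag == 0) return(NULL)
    start0 <- (seq_len(nfrag) - 1L) * fragment_length # 0-based
    data.frame(
      id = paste(species, names(contigs)[ci], start0, sep = "|"),
      species = species,
      contig = names(contigs)[ci],
      start = start0,
      seq = substring(contigs[ci], start0 + 1L, start0 + fragment_length),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Uniformly subsample fragments without replacement
#'
#' Balances database size across species with different genome sizes.
#' Requesting more fragments than exist keeps them all, with a warning, so
#' that small simulated genomes remain usable.
#'
#' @param fragments a fragment data.frame from [tile_fragments()].
#' @param n number of fragments to keep.
#' @param seed integer seed; the draw is deterministic given it.
#' @return subset of `fragments` (labels and sequences verbatim).
#' @export
sample_fragments <- function(fragments, n, seed = 1L) {
  if (n >= nrow(fragments)) {
    if (n > nrow(fragments))
      warning("requested ", n, " fragments but only ", nrow(fragments),
              " available; keeping all")
    return(fragments)
  }
  with_seed(seed, fragments[sort(sample.int(nrow(fragments), n)), , drop = FALSE])
}

#' Build a balanced, species-tagged fragment database
#'
#' Tiles every species' genome into `fragment_length` fragments, subsamples
#' `n_per_species` fragments per species so each contributes equally
#' regardless of assembly size, and attaches a k-mer index over the forward
#' strand (queries are searched on both strands by the aligner).
#'
#' @param genomes a `genome_set`, or a named list of species entries each with
#'   a `nuclear` (or `mito`) component.
#' @param fragment_length fragment size in bases.
#' @param n_per_species fragments retained per species; `Inf` keeps all (used
#'   for whole-mitogenome databases, which are not subsampled).
#' @param seed integer seed for the subsampling draws.
#' @param k k-mer size of the index (classic blastn word size 11 by default).
#' @param what `"nuclear"` or `"mito"`: which sequence compartment to tile.
#' @return a `fragment_db`: fragment table, parameters and k-mer index.
#' @export
build_fragment_db <- function(genomes, fragment_length = 100L,
                              n_per_species = Inf, seed = 1L, k = 11L,
                              what = c("nuclear", "mito")) {
  what <- match.arg(what)
  species <- if (inherits(genomes, "genome_set")) genomes$species else genomes
  if (length(species) == 0) stop("no species in genome set")
  tabs <- lapply(names(species), function(nm) {
    seqs <- species[[nm]][[what]]
    if (is.null(seqs)) stop("species ", nm, " lacks a ", what, " sequence")
    if (what == "mito") names(seqs) <- "mito"
    fr <- tile_fragments(seqs, fragment_length, species = nm)
    if (is.finite(n_per_species))
      fr <- sample_fragments(fr, n_per_species, seed = seed + match(nm, names(species)))
    fr
  })
  frags <- do.call(rbind, tabs)
  rownames(frags) <- NULL
  db <- structure(list(
    fragments = frags,
    fragment_length = as.integer(fragment_length),
    n_per_species = n_per_species,
    seed = as.integer(seed),
    k = as.integer(k),
    total_length = sum(nchar(frags$seq)),
    index = NULL
  ), class = "fragment_db")
  build_index(db, k)
}

#' Attach (or rebuild) the k-mer index of a fragment database
#'
#' Indexes every exact k-mer occurrence of every fragment (forward strand) in
#' a counting-sort postings table so seed lookup is O(1) per query k-mer.
#'
#' @param db a `fragment_db`.
#' @param k k-mer size, `1 <= k <= 13` and at most `fragment_length`.
#' @return `db` with `$index` populated and `$k` updated.
#' @export
build_index <- function(db, k = db$k) {
  stopifnot(inherits(db, "fragment_db"))
  if (k <= 0) stop("k must be positive")
  if (k > db$fragment_length) stop("k exceeds fragment_length")
  db$index <- cpp_build_kmer_index(db$fragments$seq, as.integer(k))
  db$k <- as.integer(k)
  db
}

#' Look up the postings of one k-mer
#'
#' @param db an indexed `fragment_db`.
#' @param kmer a string of length `db$k`.
#' @return data.frame of (`fragment_id`, `species`, `offset`) for every exact
#'   occurrence; zero rows when the k-mer is absent.
#' @export
kmer_lookup <- function(db, kmer) {
  stopifnot(inherits(db, "fragment_db"), !is.null(db$index))
  m <- cpp_kmer_postings(db$index$offsets, db$index$frag, db$index$pos,
                         db$k, kmer)
  data.frame(fragment_id = db$fragments$id[m[, 1]],
             species = db$fragments$species[m[, 1]],
             offset = m[, 2],
             stringsAsFactors = FALSE)
}

#' @export
print.fragment_db <- function(x, ...) {
  cat("fragment_db:", nrow(x$fragments), "fragments of",
      x$fragment_length, "bp,", x$total_length, "bp total\n")
  print(table(x$fragments$species))
  cat("k-mer index: k =", x$k, "\n")
  invisible(x)
}
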