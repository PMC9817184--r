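#' Quality-filter a read set
#'
#' Mirrors a standard short-read QC pass: 3' bases are trimmed while their
#' Phred quality is below `min_phred`; reads shorter than `min_len` after
#' trimming are dropped; reads with more than `max_masked` masked (`N`) bases
#' are dropped.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33) columns.
#' @param min_phred minimum 3' base quality retained (default 30).
#' @param min_len minimum post-trim read length (default 30).
#' @param max_masked maximum tolerated masked bases per read (default 30).
#' @return the surviving reads, trimmed, with attributes `n_input`,
#'   `n_trimmed`, `n_dropped_short`, `n_dropped_masked`.
#' @export
quality_filter <- function(reads, min_phred = 30L, min_len = 30L,
                           max_masked = 30L) {
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad))
    stop("malformed record (sequence/quality length mismatch): ",
         reads$id[bad[1]])
  n_in <- nrow(reads)
  keep_len <- vapply(reads$qual, function(q) {
    qv <- utf8ToInt(q) - 33L
    ok <- which(qv >= min_phred)
    if (length(ok)) max(ok) else 0L
  }, integer(1), USE.NAMES = FALSE)
  trimmed <- keep_len < nchar(reads$seq)
  reads$seq <- substring(reads$seq, 1L, keep_len)
  reads$qual <- substring(reads$qual, 1L, keep_len)
  long_enough <- keep_len >= min_len
  n_masked <- nchar(reads$seq) - nchar(gsub("N", "", reads$seq, fixed = TRUE))
  unmasked <- n_masked <= max_masked
  out <- reads[long_enough & unmasked, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_input") <- n_in
  attr(out, "n_trimmed") <- sum(trimmed)
  attr(out, "n_dropped_short") <- sum(!long_enough)
  attr(out, "n_dropped_masked") <- sum(long_enough & !unmasked)
  out
}

# species achieving the minimal E (maximal bit score) within relative
# tolerance; the tie rule operates at bit-score level
top_species_of <- function(species, bitscore, tol = 1e-6) {
  bmax <- max(bitscore)
  unique(species[bitscore >= bmax - tol * abs(bmax)])
}

#' Best-hit outcome for one read's alignments
#'
#' Keeps the alignment with the lowest E-value. If two or more distinct
#' species tie for the lowest E (bit scores equal within relative tolerance
#' `tol`), the read is discarded as a tie; multiple tied fragments of the
#' same species do not cause a discard. An empty alignment set is a no-hit.
#'
#' @param alignments alignment rows of a single read ([align_read()] output).
#' @param tol relative bit-score tolerance defining a tie.
#' @return list with `outcome` (`"assigned"`, `"tie_discarded"`, `"no_hit"`),
#'   and for assignments `species`, `fragment_id`, `bitscore`, `evalue`; for
#'   ties the tied `species` set.
#' @export
best_hit <- function(alignments, tol = 1e-6) {
  if (is.null(alignments) || nrow(alignments) == 0)
    return(list(outcome = "no_hit"))
  tops <- top_species_of(alignments$species, alignments$bitscore, tol)
  if (length(tops) > 1)
    return(list(outcome = "tie_discarded", species = sort(tops)))
  i <- which.max(alignments$bitscore)
  list(outcome = "assigned", species = alignments$species[i],
       fragment_id = alignments$fragment_id[i],
       bitscore = alignments$bitscore[i], evalue = alignments$evalue[i])
}

#' Best-hit assignment table for a read batch
#'
#' Applies the [best_hit()] rule to every read: reads absent from the
#' alignment table are no-hits.
#'
#' @param alignments output of [align_reads()].
#' @param reads the read set the alignments came from (defines the universe
#'   of queries and their order).
#' @param tol relative bit-score tolerance defining a tie.
#' @return data.frame with one row per read: `read_id`, `outcome`, `species`
#'   (NA unless assigned), `bitscore`, `evalue`, `tie_species`
#'   (comma-separated, NA unless tied).
#' @export
assign_best_hits <- function(alignments, reads, tol = 1e-6) {
  n <- nrow(reads)
  outcome <- rep("no_hit", n)
  species <- rep(NA_character_, n)
  bitscore <- rep(NA_real_, n)
  evalue <- rep(NA_real_, n)
  tie_species <- rep(NA_character_, n)
  if (nrow(alignments)) {
    bmax <- tapply(alignments$bitscore, alignments$read_idx, max)
    ridx <- as.integer(names(bmax))
    top <- alignments$bitscore >=
      (bmax[as.character(alignments$read_idx)] -
         tol * abs(bmax[as.character(alignments$read_idx)]))
    tops <- alignments[top, , drop = FALSE]
    nsp <- tapply(tops$species, tops$read_idx, function(s) length(unique(s)))
    tied <- ridx[nsp[as.character(ridx)] > 1]
    outcome[ridx] <- "assigned"
    outcome[tied] <- "tie_discarded"
    # representative best row per assigned read
    ord <- order(tops$read_idx, -tops$bitscore)
    first <- !duplicated(tops$read_idx[ord])
    rep_rows <- tops[ord, , drop = FALSE][first, , drop = FALSE]
    assigned <- setdiff(ridx, tied)
    rr <- rep_rows[match(assigned, rep_rows$read_idx), , drop = FALSE]
    species[assigned] <- rr$species
    bitscore[assigned] <- rr$bitscore
    evalue[assigned] <- rr$evalue
    if (length(tied)) {
      tie_species[tied] <- vapply(tied, function(r) {
        paste(sort(unique(tops$species[tops$read_idx == r])), collapse = ",")
      }, "")
    }
  }
  data.frame(read_id = reads$id, outcome = outcome, species = species,
             bitscore = bitscore, evalue = evalue, tie_species = tie_species,
             stringsAsFactors = FALSE)
}

#' Census of unique best hits per species
#'
#' Tallies assigned reads per species; proportions are over assigned reads
#' only (unique best hits), with ties and no-hits reported separately.
#' Invariant: `n_assigned + n_tie_discarded + n_no_hit` equals the number of
#' queries, and proportions sum to 1 whenever any read is assigned.
#'
#' @param assignments output of [assign_best_hits()].
#' @param species optional character vector fixing the census rows (species
#'   with zero hits then appear with count 0).
#' @return a `hit_census`: `counts`, `proportions`, `n_assigned`,
#'   `n_tie_discarded`, `n_no_hit`, `n_total`.
#' @export
census <- function(assignments, species = NULL) {
  asg <- assignments[assignments$outcome == "assigned", , drop = FALSE]
  lev <- species %||% sort(unique(asg$species))
  counts <- table(factor(asg$species, levels = lev))
  counts <- setNames(as.integer(counts), lev)
  n_assigned <- sum(counts)
  structure(list(
    counts = counts,
    proportions = if (n_assigned > 0) counts / n_assigned else
      setNames(rep(NA_real_, length(lev)), lev),
    n_assigned = n_assigned,
    n_tie_discarded = sum(assignments$outcome == "tie_discarded"),
    n_no_hit = sum(assignments$outcome == "no_hit"),
    n_total = nrow(assignments)
  ), class = "hit_census")
}

#' Build a census object from per-species counts
#'
#' For assembling a `hit_census` from externally stored counts (e.g. a census
#' TSV written by [write_census_tsv()]).
#'
#' @param counts named integer vector of unique-best-hit counts per species.
#' @param n_tie_discarded,n_no_hit optional tallies of the other outcomes.
#' @return a `hit_census`.
#' @export
census_from_counts <- function(counts, n_tie_discarded = 0L, n_no_hit = 0L) {
  counts <- setNames(as.integer(counts), names(counts))
  n <- sum(counts)
  structure(list(
    counts = counts,
    proportions = if (n > 0) counts / n else
      setNames(rep(NA_real_, length(counts)), names(counts)),
    n_assigned = n,
    n_tie_discarded = as.integer(n_tie_discarded),
    n_no_hit = as.integer(n_no_hit),
    n_total = n + as.integer(n_tie_discarded) + as.integer(n_no_hit)
  ), class = "hit_census")
}

#' @export
print.hit_census <- function(x, ...) {
  cat(sprintf("hit_census: %d queries | %d assigned, %d tie-discarded, %d no-hit\n",
              x$n_total, x$n_assigned, x$n_tie_discarded, x$n_no_hit))
  if (x$n_assigned > 0) {
    tab <- data.frame(species = names(x$counts), count = x$counts,
                      proportion = round(x$proportions, 4))
    rownames(tab) <- NULL
    print(tab[order(-tab$count), ], row.names = FALSE)
  }
  invisible(x)
}

#' Nuclear best-hit census of a read set
#'
#' Convenience composition: align, assign best hits with the cross-species
#' tie discard, and census.
#'
#' @param reads a read set (after [quality_filter()]).
#' @param db an indexed nuclear `fragment_db`.
#' @param params an [alignment_params()].
#' @param species optional fixed census rows.
#' @return a `hit_census`.
#' @export
hit_census <- function(reads, db, params = alignment_params(), species = NULL) {
  aln <- align_reads(reads, db, params)
  census(assign_best_hits(aln, reads), species %||% unique(db$fragments$species))
}

#' Mitochondrial census for dam identification
#'
#' Runs the same best-hit census against a mitochondria-only database (whole
#' mitogenomes tiled, no subsampling). Nuclear-origin reads typically fail
#' the E-value ceiling and land in `n_no_hit`.
#'
#' @param reads a read set.
#' @param mito_db `fragment_db` built from mitochondrial sequences.
#' @param params an [alignment_params()].
#' @return a `hit_census` over reads hitting the mito database.
#' @export
mito_census <- function(reads, mito_db, params = alignment_params()) {
  stopifnot(inherits(mito_db, "fragment_db"))
  if (nrow(mito_db$fragments) == 0) stop("empty mitochondrial database")
  hit_census(reads, mito_db, params)
}
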