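#' Alignment and Karlin-Altschul scoring parameters
#'
#' Scoring follows the classic nucleotide scheme: match +1, mismatch -2, and
#' affine gaps costing `gap_open + L * gap_extend` for a gap of length `L`.
#' Raw scores S are converted to bit scores `S' = (lambda S - ln K) / ln 2`
#' and E-values `E = m n 2^(-S')`, with `m` the query length and `n` the total
#' database length. `lambda` and `K` default to the standard ungapped values
#' for the +1/-2 scheme; since the census uses E-values only to rank hits and
#' detect cross-species ties, the ranking is insensitive to their exact
#' values.
#'
#' @param match,mismatch match score and mismatch penalty (mismatch negative).
#' @param gap_open,gap_extend affine gap magnitudes (positive).
#' @param lambda,K Karlin-Altschul parameters.
#' @param e_max E-value ceiling; alignments above it are discarded.
#' @param min_seed minimum number of shared k-mers to attempt an extension.
#' @param band half-width (in diagonals) of the banded extension around the
#'   seed diagonals.
#' @param max_kmer_hits seeds occurring in more postings than this are skipped
#'   as repetitive.
#' @return an `alignment_params` list.
#' @export
alignment_params <- function(match = 1L, mismatch = -2L,
                             gap_open = 5L, gap_extend = 2L,
                             lambda = 1.28, K = 0.46,
                             e_max = 1e-3, min_seed = 1L, band = 15L,
                             max_kmer_hits = 10000L) {
  stopifnot(lambda > 0, K > 0, e_max > 0, match > 0, mismatch < 0,
            gap_open >= 0, gap_extend > 0, band >= 0, min_seed >= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, e_max = e_max,
                 min_seed = as.integer(min_seed), band = as.integer(band),
                 max_kmer_hits = as.integer(max_kmer_hits)),
            class = "alignment_params")
}

#' Bit score of a raw alignment score
#' @param score raw local alignment score.
#' @param params an [alignment_params()].
#' @return bit score `(lambda * score - ln K) / ln 2`.
#' @export
bit_score <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

#' Karlin-Altschul E-value
#' @param score raw local alignment score.
#' @param m query length in bases.
#' @param n total database length in bases.
#' @param params an [alignment_params()].
#' @return expected number of chance alignments scoring at least `score`.
#' @export
karlin_altschul_evalue <- function(score, m, n, params) {
  m * n * 2^(-bit_score(score, params))
}

# smallest raw score that could still pass e_max for the shortest query
min_reportable_score <- function(m_min, n, params) {
  bit_needed <- log2(m_min * n / params$e_max)
  s <- (bit_needed * log(2) + log(params$K)) / params$lambda
  max(1L, as.integer(floor(s)))
}

#' Reverse complement of DNA strings
#' @param x character vector of sequences (non-ACGT bases become N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) as.character(cpp_revcomp(x))

#' Exact Smith-Waterman local alignment score
#'
#' Full-matrix affine-gap dynamic programming, no seeding or banding. This is
#' the package's reference scorer: the seed-and-extend path is tested against
#' it, and it is itself cross-checked against an independent implementation
#' in the test suite.
#'
#' @param a,b nucleotide strings.
#' @param params an [alignment_params()].
#' @return integer raw score (0 when no positive-scoring local alignment).
#' @export
smith_waterman_score <- function(a, b, params = alignment_params()) {
  cpp_sw_score(a, b, params$match, params$mismatch,
               params$gap_open, params$gap_extend)
}

#' Align a batch of reads against a fragment database
#'
#' Seed-and-extend: shared k-mers between a read and a fragment (either read
#' strand; the database stores the forward strand only) nominate candidate
#' fragments, which are scored by banded affine Smith-Waterman over the
#' seeded diagonals +/- `band`. Per (read, fragment) the best score across
#' strands is kept; alignments with `E > e_max` are discarded.
#'
#' @param reads a `read_set` data.frame (columns `id`, `seq`) or a character
#'   vector of sequences.
#' @param db an indexed `fragment_db`.
#' @param params an [alignment_params()].
#' @return data.frame with one row per surviving (read, fragment) pair:
#'   `read_idx`, `read_id`, `fragment_id`, `species`, `strand`, `score`,
#'   `bitscore`, `evalue`. Reads with no row had no hit at `e_max`.
#' @export
align_reads <- function(reads, db, params = alignment_params()) {
  stopifnot(inherits(db, "fragment_db"), !is.null(db$index))
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("q", seq_along(reads)), seq = reads,
                        stringsAsFactors = FALSE)
  }
  if (nrow(reads) == 0) {
    return(data.frame(read_idx = integer(0), read_id = character(0),
                      fragment_id = character(0), species = character(0),
                      strand = character(0), score = integer(0),
                      bitscore = numeric(0), evalue = numeric(0)))
  }
  n <- db$total_length
  m_min <- min(nchar(reads$seq))
  min_report <- min_reportable_score(max(m_min, db$k), n, params)
  hits <- cpp_align_batch(reads$seq, db$fragments$seq,
                          db$index$offsets, db$index$frag, db$index$pos,
                          db$k, params$match, params$mismatch,
                          params$gap_open, params$gap_extend,
                          params$band, params$min_seed, min_report,
                          params$max_kmer_hits)
  m <- nchar(reads$seq)[hits$read]
  bits <- bit_score(hits$score, params)
  ev <- m * n * 2^(-bits)
  keep <- ev <= params$e_max
  data.frame(read_idx = hits$read[keep],
             read_id = reads$id[hits$read[keep]],
             fragment_id = db$fragments$id[hits$frag[keep]],
             species = db$fragments$species[hits$frag[keep]],
             strand = ifelse(hits$strand[keep] > 0, "+", "-"),
             score = hits$score[keep],
             bitscore = bits[keep],
             evalue = ev[keep],
             stringsAsFactors = FALSE)
}

#' Align a single read
#'
#' Convenience wrapper over [align_reads()] for one query sequence.
#'
#' @param read one nucleotide string.
#' @param db an indexed `fragment_db`.
#' @param params an [alignment_params()].
#' @return alignment data.frame as in [align_reads()] (possibly zero rows; a
#'   read shorter than the seed size can produce no hit).
#' @export
align_read <- function(read, db, params = alignment_params()) {
  align_reads(c(read), db, params)
}
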