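#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a genome set to per-species FASTA files
#'
#' Nuclear contigs go to `<species>.fa`, the mitogenome to `<species>.mito.fa`.
#'
#' @param genomes a `genome_set`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_genomes_fasta <- function(genomes, dir) {
  stopifnot(inherits(genomes, "genome_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(genomes$species)) {
    sp <- genomes$species[[nm]]
    p1 <- file.path(dir, paste0(nm, ".fa"))
    write_fasta(sp$nuclear, p1)
    p2 <- file.path(dir, paste0(nm, ".mito.fa"))
    write_fasta(setNames(sp$mito, paste0(nm, "_mito")), p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}

#' Write a read set as FASTQ (Phred+33)
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual)))
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' Read a FASTQ file as a read-set data.frame
#' @param path FASTQ file.
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_reads_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a fragment database as FASTA plus a metadata sidecar
#'
#' The sidecar (JSON) records fragment length, per-species sample size, seed
#' and k so a database build is reproducible bit-exactly.
#'
#' @param db a `fragment_db`.
#' @param stem output stem; writes `<stem>.fa` and `<stem>.json`.
#' @return the two paths, invisibly.
#' @export
write_fragment_db <- function(db, stem) {
  stopifnot(inherits(db, "fragment_db"))
  fa <- paste0(stem, ".fa")
  js <- paste0(stem, ".json")
  write_fasta(setNames(db$fragments$seq, db$fragments$id), fa)
  jsonlite::write_json(list(fragment_length = db$fragment_length,
                            n_per_species = db$n_per_species,
                            seed = db$seed, k = db$k,
                            n_fragments = nrow(db$fragments),
                            total_length = db$total_length),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(fa, js))
}

#' Write a census as TSV
#' @param x a `hit_census` or `sister_census`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_census_tsv <- function(x, path) {
  tab <- data.frame(species = names(x$counts), count = x$counts,
                    proportion = x$proportions)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
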