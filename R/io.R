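#' Write a read-pair table as two FASTQ files
#'
#' Mate identifiers encode the pair id and mate side (`/1`, `/2`); qualities
#' are constant Phred+33 `I`.
#'
#' @param reads tibble with `read_id`, `seq1`, `seq2` (as from [sample_reads()]).
#' @param path1,path2 output paths for the forward and reverse mate files.
#' @return invisibly, `c(path1, path2)`.
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  .write_fastq(reads$seq1, paste0(reads$read_id, "/1"), path1)
  .write_fastq(reads$seq2, paste0(reads$read_id, "/2"), path2)
  invisible(c(path1, path2))
}

.write_fastq <- function(seqs, ids, path) {
  xs <- Biostrings::DNAStringSet(setNames(seqs, ids))
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(xs, path, format = "fastq", qualities = qual)
}

#' Read a FASTQ mate pair back into a read table
#'
#' @param path1,path2 FASTQ files for mates 1 and 2; pairing is recovered
#'   from the shared identifier stem.
#' @return tibble with `read_id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  id1 <- sub("/1$", "", sub(" .*", "", names(r1)))
  id2 <- sub("/2$", "", sub(" .*", "", names(r2)))
  if (length(r1) != length(r2)) abort("FASTQ mate files differ in read count")
  m <- match(id1, id2)
  if (anyNA(m)) abort("mate pairing could not be recovered from identifiers")
  tibble::tibble(read_id = id1,
                 seq1 = unname(as.character(r1)),
                 seq2 = unname(as.character(r2)[m]))
}

#' Read a single-record FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(xs), sub(" .*", "", names(xs)))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a BED file of insertion loci
#'
#' Accepts 3+ column BED (0-based, half-open). A locus is a breakpoint;
#' zero-length and 1 bp intervals are both accepted and collapse to their
#' start coordinate.
#'
#' @param path BED path.
#' @return tibble with `chrom`, `start`, `end`, and `name` when present.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(fields))
  if (ncol < 3) abort("BED records need at least 3 columns")
  tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    name = if (ncol >= 4) vapply(fields, `[[`, "", 4L) else NA_character_
  )
}

#' Write a BED file
#'
#' @param bed tibble with `chrom`, `start`, `end` and optional further columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
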