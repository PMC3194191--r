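# Minimal SAM dialect (spec v1): QNAME FLAG RNAME POS MAPQ CIGAR RNEXT PNEXT
# TLEN SEQ QUAL + optional NM:i tag. Secondary alignments carry flag 0x100.
# SAM positions are 1-based; everything internal is 0-based half-open and
# converted at this boundary.

.sam_flag <- function(mate, strand, unmapped, mate_unmapped, mate_strand,
                      secondary) {
  f <- 1L                                    # paired
  if (unmapped) f <- f + 4L
  if (mate_unmapped) f <- f + 8L
  if (!unmapped && strand == 1L) f <- f + 16L
  if (!mate_unmapped && mate_strand == 1L) f <- f + 32L
  f <- f + if (mate == 1L) 64L else 128L
  if (secondary) f <- f + 256L
  f
}

#' Export a mapping table to SAM
#'
#' Writes the package's minimal SAM dialect: one record per mapping location
#' (first hit primary, further hits secondary), plus one unmapped record per
#' unmapped mate so every read appears. Sequence and quality are written as
#' `*` for secondary records.
#'
#' @param mapping a `mapping_table` from [map_reads()].
#' @param reads the read table the mapping was computed from.
#' @param path output path.
#' @param rname reference name to emit.
#' @return invisibly, `path`.
#' @export
write_sam <- function(mapping, reads, path, rname = "reference") {
  l <- attr(mapping, "read_length")
  n <- attr(mapping, "n_pairs")
  ref_len <- attr(mapping, "reference_length")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", rname, ref_len))
  key <- paste(mapping$pair_id, mapping$mate)
  first_hit <- !duplicated(key)
  # mate-level summaries for flag construction
  mapped <- matrix(FALSE, n, 2)
  mstrand <- matrix(0L, n, 2)
  mapped[cbind(mapping$pair_id, mapping$mate)] <- TRUE
  prim <- mapping[first_hit, ]
  mstrand[cbind(prim$pair_id, prim$mate)] <- prim$strand
  rec_for <- function(pid, mate, pos, strand, nm, secondary) {
    unm <- is.na(pos)
    other <- 3L - mate
    seqq <- if (secondary) "*" else if (mate == 1L) {
      if (strand == 1L) revcomp(reads$seq1[pid]) else reads$seq1[pid]
    } else {
      if (strand == 1L) revcomp(reads$seq2[pid]) else reads$seq2[pid]
    }
    flag <- .sam_flag(mate, strand, unm, !mapped[pid, other], mstrand[pid, other],
                      secondary)
    paste(reads$read_id[pid], flag,
          if (unm) "*" else rname,
          if (unm) 0L else pos + 1L,
          if (unm) 0L else 60L, if (unm) "*" else sprintf("%dM", l),
          "*", 0L, 0L, seqq,
          if (secondary || unm) "*" else strrep("I", l),
          if (unm) "" else sprintf("NM:i:%d", nm),
          sep = "\t")
  }
  out <- character(nrow(mapping))
  for (i in seq_len(nrow(mapping))) {
    out[i] <- rec_for(mapping$pair_id[i], mapping$mate[i], mapping$pos[i],
                      mapping$strand[i], mapping$nm[i], !first_hit[i])
  }
  unmapped_rec <- character(0)
  for (pid in seq_len(n)) {
    for (mate in 1:2) {
      if (!mapped[pid, mate]) {
        unmapped_rec <- c(unmapped_rec,
                          rec_for(pid, mate, NA_integer_, 0L, 0L, FALSE))
      }
    }
  }
  readr::write_lines(sub("\t$", "", c(hdr, out, unmapped_rec)), path)
  invisible(path)
}

#' Load read mappings from a SAM file
#'
#' Reads the minimal SAM dialect written by [write_sam()] (or any SAM whose
#' records carry QNAME/FLAG/RNAME/POS/SEQ and, optionally, an `NM:i` tag).
#' Primary and secondary alignments are both ingested; unmapped flags are
#' honored. All reads must share one fixed length, and both mates of every
#' pair must be present.
#'
#' @param path SAM path.
#' @param reads optional read table; when supplied, pair order follows it,
#'   otherwise pairs are ordered by first appearance.
#' @return a `mapping_table`, as from [map_reads()].
#' @export
load_sam <- function(path, reads = NULL) {
  lines <- readr::read_lines(path)
  ref_len <- NA_integer_
  sq <- grep("^@SQ", lines, value = TRUE)
  if (length(sq)) {
    ln <- sub(".*\tLN:([0-9]+).*", "\\1", sq[1])
    ref_len <- as.integer(ln)
  }
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) abort("SAM file contains no alignment records")
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 10)) abort("malformed SAM record: fewer than 10 fields")
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  pos1 <- as.integer(vapply(f, `[[`, "", 4L))
  seqf <- vapply(f, `[[`, "", 10L)
  nm <- vapply(f, function(x) {
    t <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(t)) as.integer(sub("NM:i:", "", t[1])) else 0L
  }, 0L)
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)
  unmapped <- bitwAnd(flag, 4L) > 0L
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, 1L, 0L)
  lens <- unique(nchar(seqf[seqf != "*"]))
  if (length(lens) > 1) abort("mixed read lengths in SAM input")
  if (length(lens) == 0) abort("no sequence-bearing records in SAM input")
  l <- lens[1]
  if (is.null(reads)) {
    ids <- unique(qname)
  } else {
    ids <- reads$read_id
  }
  pid <- match(qname, ids)
  if (anyNA(pid)) abort("SAM contains reads absent from the read table")
  seen <- matrix(FALSE, length(ids), 2)
  seen[cbind(pid, mate)] <- TRUE
  if (!all(seen)) abort("missing mate records: every pair needs both mates")
  keep <- !unmapped
  tbl <- tibble::tibble(pair_id = pid[keep], mate = mate[keep],
                        pos = pos1[keep] - 1L, strand = strand[keep],
                        nm = nm[keep])
  tbl <- dplyr::arrange(tbl, .data$pair_id, .data$mate, .data$pos)
  structure(tbl, read_length = l, d = max(c(tbl$nm, 0L)),
            n_pairs = length(ids), read_ids = ids,
            reference_length = ref_len,
            class = c("mapping_table", class(tbl)))
}
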