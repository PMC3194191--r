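#' Generate a uniform-random reference sequence
#'
#' Draws `length` bases i.i.d. uniform over A, C, G, T. A synthetic
#' stand-in for a real chromosome at desk scale.
#'
#' @param length reference length in bp.
#' @param seed optional RNG seed; the same seed yields the same sequence.
#' @return a single character string of `length` bases.
#' @export
#' @examples
#' generate_reference(50, seed = 1)
generate_reference <- function(length, seed = NULL) {
  .stopifnot_scalar_count(length, "length")
  .with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  })
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant insertions into a reference, producing a donor genome and truth set
#'
#' Insertion lengths are drawn Normal(`insert_size_mean`, `insert_size_sd`),
#' rounded and floored at `min_insert_size`. Loci are drawn uniformly subject
#' to a minimum spacing of `2 * (delta_max + l)` plus the largest insertion
#' length, so every insertion keeps the clean flanking segment the extension
#' base case assumes. Unique insertions (`case1_unique`) are uniform-random
#' sequence; copied insertions (`case2_copied`) duplicate a uniformly chosen
#' reference window verbatim; mixed insertions (`case3_mixed`) take a copied
#' segment and insert a unique segment of equal total weight into its middle
#' (an insertion inside an insertion).
#'
#' @param reference reference sequence (single string).
#' @param spec a [simulation_spec()]; `seed + 1` drives the draws here
#'   (each simulation stage uses its own seed offset so the streams are
#'   independent).
#' @return a list with elements `donor` (character string) and `truth`
#'   (tibble: `insertion_id`, `ref_locus` (0-based), `donor_locus`,
#'   `category`, `length`, `sequence`, `copied_source_locus`).
#' @export
plant_insertions <- function(reference, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  reference <- .check_dna(reference, "reference")
  L <- nchar(reference)
  n <- spec$n_insertions
  l <- spec$read_length
  dmax <- spec$frag_mean + 3 * spec$frag_sd
  if (n == 0) {
    return(list(donor = reference, truth = .empty_truth()))
  }
  .with_seed(spec$seed + 1L, {
    len <- pmax(spec$min_insert_size,
                as.integer(round(rnorm(n, spec$insert_size_mean, spec$insert_size_sd))))
    spacing <- as.integer(ceiling(2 * (dmax + l) + max(len)))
    margin <- spacing
    slack <- L - 2 * margin - (n - 1) * spacing
    if (slack < n) {
      abort(sprintf(paste0(
        "reference too short: %d insertions require spacing >= %d bp ",
        "(2*(delta_max + l) + max insertion length) plus end margins, ",
        "but only %d bp of slack remain"), n, spacing, slack))
    }
    offs <- sort(sample.int(slack, n))
    loci <- margin + offs + (seq_len(n) - 1L) * spacing  # 0-based ref positions
    seqs <- character(n)
    src <- rep(NA_integer_, n)
    # copy sources must not straddle an insertion locus, or the source copy
    # would be interrupted in the donor
    draw_source <- function(w) {
      repeat {
        s <- sample.int(L - w + 1L, 1L) - 1L
        if (!any(loci > s & loci < s + w)) return(s)
      }
    }
    for (i in seq_len(n)) {
      seqs[i] <- switch(spec$category,
        case1_unique = .random_dna(len[i]),
        case2_copied = {
          s <- draw_source(len[i])
          src[i] <- s
          substr(reference, s + 1L, s + len[i])
        },
        case3_mixed = {
          hc <- len[i] %/% 2L            # copied weight
          hu <- len[i] - hc              # unique weight
          s <- draw_source(hc)
          src[i] <- s
          copied <- substr(reference, s + 1L, s + hc)
          mid <- hc %/% 2L
          paste0(substr(copied, 1L, mid), .random_dna(hu),
                 substr(copied, mid + 1L, hc))
        })
    }
    donor_locus <- loci + c(0L, cumsum(len)[-n])
    pieces <- character(2L * n + 1L)
    prev <- 0L
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- substr(reference, prev + 1L, loci[i])
      pieces[2L * i] <- seqs[i]
      prev <- loci[i]
    }
    pieces[2L * n + 1L] <- substr(reference, prev + 1L, L)
    donor <- paste(pieces, collapse = "")
    truth <- tibble::tibble(
      insertion_id = sprintf("ins%04d", seq_len(n)),
      ref_locus = as.integer(loci),
      donor_locus = as.integer(donor_locus),
      category = spec$category,
      length = len,
      sequence = seqs,
      copied_source_locus = src
    )
    list(donor = donor, truth = truth)
  })
}

.empty_truth <- function() {
  tibble::tibble(
    insertion_id = character(0), ref_locus = integer(0),
    donor_locus = integer(0), category = character(0), length = integer(0),
    sequence = character(0), copied_source_locus = integer(0)
  )
}

#' Excise truth insertions from a donor, restoring the reference
#'
#' Inverse of [plant_insertions()]; used to verify the round-trip invariant.
#'
#' @param donor donor sequence.
#' @param truth truth tibble from [plant_insertions()].
#' @return the reconstructed reference string.
#' @export
excise_insertions <- function(donor, truth) {
  if (nrow(truth) == 0) return(donor)
  truth <- dplyr::arrange(truth, .data$donor_locus)
  pieces <- character(nrow(truth) + 1L)
  prev <- 0L
  for (i in seq_len(nrow(truth))) {
    pieces[i] <- substr(donor, prev + 1L, truth$donor_locus[i])
    prev <- truth$donor_locus[i] + truth$length[i]
  }
  pieces[nrow(truth) + 1L] <- substr(donor, prev + 1L, nchar(donor))
  paste(pieces, collapse = "")
}

#' Sample paired-end reads from a donor genome
#'
#' Emits `round(coverage * |donor| / (2 l))` pairs. Each fragment starts
#' uniformly, with length drawn Normal(`frag_mean`, `frag_sd`) and re-drawn
#' until it falls inside `[mu - 3 sigma, mu + 3 sigma]` (the hard-interval
#' assumption of the insert-size model). The forward mate is the first `l`
#' bases of the fragment; the reverse mate is the reverse complement of the
#' last `l`. Substitution errors are applied i.i.d. at `error_rate` (the
#' substituted base is always different from the original).
#'
#' @param donor donor sequence (single string).
#' @param spec a [simulation_spec()]; `seed + 2` seeds the read draws so
#'   planting and sampling are independently reproducible.
#' @return tibble with `read_id`, `seq1`, `seq2` and attribute
#'   `frag_truth` (tibble of 0-based fragment starts and lengths).
#' @export
sample_reads <- function(donor, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  L <- nchar(donor)
  l <- spec$read_length
  mu <- spec$frag_mean
  s <- spec$frag_sd
  if (L <= mu + 6 * s) abort("donor shorter than a maximal fragment")
  n <- as.integer(round(spec$coverage * L / (2 * l)))
  .with_seed(spec$seed + 2L, {
    flen <- as.integer(round(rnorm(n, mu, s)))
    lo <- mu - 3 * s
    hi <- mu + 3 * s
    bad <- which(flen < lo | flen > hi)
    while (length(bad) > 0) {
      flen[bad] <- as.integer(round(rnorm(length(bad), mu, s)))
      bad <- bad[flen[bad] < lo | flen[bad] > hi]
    }
    start <- as.integer(floor(runif(n) * (L - flen + 1)))  # 0-based
    mates <- .extract_pairs_cpp(donor, start, flen, l)
    seq1 <- mates$seq1
    seq2 <- mates$seq2
    if (spec$error_rate > 0) {
      seq1 <- .add_errors(seq1, spec$error_rate)
      seq2 <- .add_errors(seq2, spec$error_rate)
    }
    out <- tibble::tibble(
      read_id = sprintf("p%07d", seq_len(n)),
      seq1 = seq1, seq2 = seq2
    )
    attr(out, "frag_truth") <- tibble::tibble(start = start, frag_len = flen)
    attr(out, "read_length") <- l
    out
  })
}

# substitution-only error model; substituted base differs from the original
.add_errors <- function(seqs, rate) {
  l <- nchar(seqs[1])
  bases <- c("A", "C", "G", "T")
  k <- rbinom(length(seqs), l, rate)
  # single-error reads (the vast majority of affected reads), vectorised
  one <- which(k == 1L)
  if (length(one)) {
    p <- sample.int(l, length(one), replace = TRUE)
    old <- substr(seqs[one], p, p)
    shift <- sample.int(3L, length(one), replace = TRUE)
    new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
    substr(seqs[one], p, p) <- new
  }
  for (i in which(k > 1L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(l, k[i])
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Run a full simulation: reference, donor, truth, reads
#'
#' Convenience wrapper chaining [generate_reference()], [plant_insertions()]
#' and [sample_reads()] under one spec.
#'
#' @param spec a [simulation_spec()].
#' @return list with `reference`, `donor`, `truth`, `reads`, `loci`
#'   (0-based insertion breakpoints) and the `spec` echo.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  reference <- generate_reference(spec$reference_length, seed = spec$seed)
  planted <- plant_insertions(reference, spec)
  reads <- sample_reads(planted$donor, spec)
  list(reference = reference, donor = planted$donor, truth = planted$truth,
       reads = reads, loci = planted$truth$ref_locus, spec = spec)
}

#' Write simulation artifacts to disk
#'
#' Writes `reference.fa`, `donor.fa` (60-column FASTA), `reads_1.fastq` /
#' `reads_2.fastq` (Phred+33, constant quality), `truth.tsv`, `loci.bed`
#' (0-based half-open single-breakpoint records) and `frag_truth.tsv`
#' (debugging sidecar; never consumed by the assembler).
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory, created if missing.
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- function(x, nm, path) {
    xs <- Biostrings::DNAStringSet(setNames(x, nm))
    Biostrings::writeXStringSet(xs, path, width = 60L)
  }
  fa(sim$reference, "reference", file.path(dir, "reference.fa"))
  fa(sim$donor, "donor", file.path(dir, "donor.fa"))
  write_fastq_pair(sim$reads, file.path(dir, "reads_1.fastq"),
                   file.path(dir, "reads_2.fastq"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(attr(sim$reads, "frag_truth"), file.path(dir, "frag_truth.tsv"))
  write_bed(tibble::tibble(chrom = "reference", start = sim$loci,
                           end = sim$loci + 1L,
                           name = sim$truth$insertion_id),
            file.path(dir, "loci.bed"))
  invisible(file.path(dir, c("reference.fa", "donor.fa", "reads_1.fastq",
                             "reads_2.fastq", "truth.tsv", "loci.bed")))
}
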