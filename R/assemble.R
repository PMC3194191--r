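#' Assemble the insertions at a set of loci
#'
#' Drives bidirectional segment extension at every insertion breakpoint.
#' The forward extension grows the left flank into the insertion; when it
#' terminates by overlapping the right flank's head, the insertion is fully
#' assembled and the contig is formed directly. Otherwise the right flank
#' is extended in the reverse direction and the two extended segments are
#' offered to [merge_adjacent()]; failing that, both fragments are reported
#' as a partial assembly. Hypothesis sets produced by divergence branching
#' are resolved by [score_and_select()] (greatest number of accounted
#' reads).
#'
#' @param reference reference sequence.
#' @param loci integer vector of 0-based insertion breakpoints.
#' @param index a `read_index` over the insertion read set.
#' @param model an [insert_size_model()].
#' @param params an [align_params()].
#' @param flank bp of reference flank used as the extension base on each
#'   side (must be at least `l + delta_max`).
#' @return tibble with one row per locus: `locus`, `status` (`"merged"`,
#'   `"partial"`, `"failed"`), `contig` (assembled local sequence; for a
#'   partial assembly the two fragments joined), `insertion` (estimated
#'   inserted sequence when determined), `n_hypotheses`, `accounted`,
#'   `reason`, `insertion_id`.
#' @export
assemble_insertions <- function(reference, loci, index, model,
                                params = align_params(), flank = 600L) {
  l <- index$l
  flank <- max(as.integer(flank), as.integer(l + model$delta_max) + l)
  n <- length(loci)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- .assemble_one(reference, loci[i], index, model, params, flank)
  }
  res <- dplyr::bind_rows(out)
  res$insertion_id <- sprintf("ins%04d", seq_len(n))
  res
}

.assemble_one <- function(reference, locus, index, model, params, flank) {
  l <- index$l
  L <- nchar(reference)
  lf_start <- max(0L, locus - flank)
  left_flank <- substr(reference, lf_start + 1L, locus)
  right_flank <- substr(reference, locus + 1L, min(L, locus + flank))
  fail <- function(reason) {
    tibble::tibble(locus = locus, status = "failed", contig = NA_character_,
                   insertion = NA_character_, n_hypotheses = 0L,
                   accounted = 0L, reason = reason)
  }
  if (nchar(left_flank) < l + model$delta_max ||
      nchar(right_flank) < l + model$delta_max) {
    return(fail("insufficient flank"))
  }
  fwd <- extend_segment(left_flank, "forward", index, params, model,
                        opposite_head = substr(right_flank, 1L, l))
  best <- score_and_select(fwd, index, params,
                           flank_left = left_flank, flank_right = right_flank)
  if (best$reason == "flank_overlap") {
    app <- best$sequence
    ins <- substr(app, 1L, nchar(app) - l)
    contig <- paste0(left_flank, app,
                     substr(right_flank, l + 1L, nchar(right_flank)))
    return(tibble::tibble(locus = locus, status = "merged", contig = contig,
                          insertion = ins, n_hypotheses = best$n_hypotheses,
                          accounted = best$accounted_read_count,
                          reason = best$reason))
  }
  # forward fell short: extend the right flank backwards and try to merge
  rev <- extend_segment(right_flank, "reverse", index, params, model,
                        opposite_head = revcomp(substr(
                          left_flank, nchar(left_flank) - l + 1L,
                          nchar(left_flank))))
  best_rev <- score_and_select(rev, index, params,
                               flank_left = left_flank,
                               flank_right = right_flank)
  left_contig <- paste0(left_flank, best$sequence)
  right_contig <- paste0(best_rev$sequence, right_flank)
  ls <- c(rep(Inf, nchar(left_flank)), best$support)
  rs <- c(best_rev$support, rep(Inf, nchar(right_flank)))
  mg <- merge_adjacent(left_contig, right_contig, l, params,
                       left_support = ls, right_support = rs)
  if (mg$merged) {
    tibble::tibble(locus = locus, status = "merged", contig = mg$sequence,
                   insertion = NA_character_,
                   n_hypotheses = best$n_hypotheses + best_rev$n_hypotheses,
                   accounted = best$accounted_read_count +
                     best_rev$accounted_read_count,
                   reason = "merge_overlap")
  } else {
    tibble::tibble(locus = locus, status = "partial",
                   contig = paste0(left_contig, right_contig),
                   insertion = NA_character_,
                   n_hypotheses = best$n_hypotheses + best_rev$n_hypotheses,
                   accounted = best$accounted_read_count +
                     best_rev$accounted_read_count,
                   reason = paste(best$reason, best_rev$reason, sep = "+"))
  }
}

#' Run the classification and assembly pipeline on an in-memory dataset
#'
#' Chains mapping, pair classification, coverage profiling, over-coverage
#' selection, insertion-read-set construction, read indexing and per-locus
#' assembly. Randomness (multi-mapper placement, over-coverage draws, N
#' replacement) comes from the caller's RNG stream.
#'
#' @param reference reference sequence.
#' @param reads read table (`read_id`, `seq1`, `seq2`).
#' @param loci 0-based insertion breakpoints.
#' @param model an [insert_size_model()], or NULL to estimate it from the
#'   mapped concordant pairs.
#' @param params an [align_params()].
#' @param d mapping substitution budget.
#' @param mapping optional precomputed `mapping_table` (e.g. from
#'   [load_sam()]); when given the internal mapper is skipped.
#' @return list with `assembly` (tibble), `irs`, `labels`, `profile`,
#'   `model`, `mapping`.
#' @export
assemble_from_reads <- function(reference, reads, loci, model = NULL,
                                params = align_params(), d = 2,
                                mapping = NULL) {
  if (is.null(mapping)) {
    ref_index <- build_reference_index(reference)
    mapping <- map_reads(reads, ref_index, d = d)
  }
  if (is.null(model)) model <- estimate_insert_model(mapping)
  labels <- classify_pairs(mapping, model)
  profile <- compute_coverage(mapping, nchar(reference))
  over <- select_over_coverage(labels, profile)
  irs <- build_irs(reads, labels, over)
  index <- build_read_index(irs)
  assembly <- assemble_insertions(reference, loci, index, model, params)
  list(assembly = assembly, irs = irs, labels = labels, profile = profile,
       model = model, mapping = mapping)
}
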