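#' Merge two adjacent extended segments into one contig
#'
#' Searches for the best ungapped suffix/prefix overlap of at least `l`
#' bases passing the mismatch-fraction threshold. When found, the overlap
#' is resolved once (no duplication); at a disagreeing overlap column the
#' base from the side with larger covering support is taken. Without a
#' qualifying overlap both fragments are returned flagged partial: only a
#' portion of the insertion between them was assembled.
#'
#' @param left,right the two extended sequences (left's tail should meet
#'   right's head).
#' @param read_length minimum overlap l.
#' @param params an [align_params()].
#' @param left_support,right_support optional per-base covering support for
#'   each sequence (defaults treat all positions as equally trusted, in
#'   which case disagreements take the left base).
#' @return list with `merged` (logical), `sequence` (merged contig or NA),
#'   `overlap`, `mismatches`.
#' @export
merge_adjacent <- function(left, right, read_length, params = align_params(),
                           left_support = NULL, right_support = NULL) {
  l <- as.integer(read_length)
  ov <- .overlap_merge_cpp(toupper(left), toupper(right), l, params$tau)
  if (ov$overlap == 0) {
    return(list(merged = FALSE, sequence = NA_character_, overlap = 0L,
                mismatches = 0L))
  }
  o <- ov$overlap
  nl <- nchar(left)
  head_part <- substr(left, 1L, nl - o)
  tail_part <- substr(right, o + 1L, nchar(right))
  left_ov <- substr(left, nl - o + 1L, nl)
  right_ov <- substr(right, 1L, o)
  if (ov$mismatches > 0) {
    lc <- strsplit(left_ov, "", fixed = TRUE)[[1]]
    rc <- strsplit(right_ov, "", fixed = TRUE)[[1]]
    dis <- which(lc != rc)
    ls <- if (is.null(left_support)) rep(Inf, nl) else left_support
    rs <- if (is.null(right_support)) rep(Inf, nchar(right)) else right_support
    for (i in dis) {
      lsup <- ls[nl - o + i]
      rsup <- rs[i]
      if (!is.na(rsup) && !is.na(lsup) && rsup > lsup) lc[i] <- rc[i]
    }
    left_ov <- paste(lc, collapse = "")
  }
  list(merged = TRUE, sequence = paste0(head_part, left_ov, tail_part),
       overlap = o, mismatches = ov$mismatches)
}

#' Levenshtein edit distance
#'
#' Unit-cost substitutions and indels, via [utils::adist()].
#'
#' @param a,b sequences.
#' @return integer edit distance.
#' @export
#' @examples
#' edit_distance("ACGT", "ACG")  # 1
edit_distance <- function(a, b) {
  as.integer(adist(a, b))
}

#' Best-placement edit distance of a truth sequence inside a contig
#'
#' Semi-global (infix) edit distance: the truth sequence slides over the
#' contig and the minimum-distance window is taken, on both strands.
#' Assembled contigs include reference flanks, so local placement is the
#' right comparison.
#'
#' @param truth_seq planted insertion sequence.
#' @param contig assembled contig (may be NA for a failed insertion).
#' @return integer distance (`nchar(truth_seq)` when the contig is missing).
#' @export
placement_distance <- function(truth_seq, contig) {
  if (is.na(contig) || !nzchar(contig)) return(nchar(truth_seq))
  fwd <- .semiglobal_edit_cpp(truth_seq, contig)
  if (fwd == 0) return(0L)
  min(fwd, .semiglobal_edit_cpp(revcomp(truth_seq), contig))
}

#' Score an assembly against the planted truth
#'
#' An insertion is assembled correctly when the best-placement edit
#' distance between its true sequence and the assembled contig is at most
#' `threshold` (10 bp in the reference protocol).
#'
#' @param assembled tibble from [assemble_insertions()] (needs
#'   `insertion_id` and `contig`).
#' @param truth truth tibble from [plant_insertions()].
#' @param threshold edit-distance margin in bp.
#' @return tibble with per-insertion `distance` and `correct`; attributes
#'   `n_correct` and `accuracy` (percent).
#' @export
score_assembly <- function(assembled, truth, threshold = 10) {
  if (!all(truth$insertion_id %in% assembled$insertion_id)) {
    abort("assembled results and truth records do not share insertion ids")
  }
  m <- match(truth$insertion_id, assembled$insertion_id)
  detail <- tibble::tibble(
    insertion_id = truth$insertion_id,
    category = truth$category,
    length = truth$length,
    status = assembled$status[m],
    distance = vapply(seq_len(nrow(truth)), function(i) {
      placement_distance(truth$sequence[i], assembled$contig[m[i]])
    }, 0L)
  )
  detail$correct <- detail$distance <= threshold
  attr(detail, "n_correct") <- sum(detail$correct)
  attr(detail, "accuracy") <- 100 * mean(detail$correct)
  attr(detail, "threshold") <- threshold
  detail
}

#' Aggregate replicate scores into an accuracy report
#'
#' Per-replicate accuracies are averaged; the spread is the sample (n-1)
#' standard deviation over replicates.
#'
#' @param replicates list of per-replicate score tibbles from
#'   [score_assembly()], or a tibble with columns `seed`, `n_insertions`,
#'   `n_correct`, `accuracy`.
#' @param config optional list echoed into the report (case label, seeds,
#'   coverage, ...).
#' @return object of class `insertion_accuracy` with `per_replicate`
#'   (tibble) and `summary` (mean and SD of accuracy, in percent).
#' @export
accuracy_report <- function(replicates, config = list()) {
  if (inherits(replicates, "data.frame")) {
    per <- tibble::as_tibble(replicates)
  } else {
    per <- purrr::imap_dfr(replicates, function(r, i) {
      tibble::tibble(replicate = i,
                     n_insertions = nrow(r),
                     n_correct = attr(r, "n_correct"),
                     accuracy = attr(r, "accuracy"))
    })
  }
  structure(
    list(per_replicate = per,
         summary = tibble::tibble(
           mean_accuracy = mean(per$accuracy),
           sd_accuracy = if (nrow(per) > 1) sd(per$accuracy) else 0,
           n_replicates = nrow(per)),
         config = config),
    class = "insertion_accuracy"
  )
}

#' @export
print.insertion_accuracy <- function(x, ...) {
  cat(sprintf("<insertion_accuracy> %d replicate(s): mean %.2f%%, SD %.2f%%\n",
              x$summary$n_replicates, x$summary$mean_accuracy,
              x$summary$sd_accuracy))
  if (length(x$config)) {
    cat("  config:", paste(names(x$config),
                           vapply(x$config, function(v) paste(v, collapse = ","), ""),
                           sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
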