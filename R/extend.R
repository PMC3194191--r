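#' Anchor window for the next unknown position
#'
#' For frontier position `pos` (0-based index of the next unknown base in
#' the segment), the anchor window is the known interval
#' `[pos - l - delta_max, pos - delta_min)`: a mate lying wholly inside it
#' can have sampled a partner that covers `pos`. Extension requires the
#' window to be fully determined, i.e. `pos >= l + delta_max`.
#'
#' @param segment the known segment sequence (single string).
#' @param pos 0-based frontier position; defaults to the segment end.
#' @param model an [insert_size_model()].
#' @param read_length mate length l.
#' @return list with `start`, `end` (0-based half-open window interval) and
#'   `sequence`.
#' @export
#' @examples
#' m <- insert_size_model(200, 25)
#' w <- anchor_window(strrep("A", 1000), 1000, m, 36)
#' c(w$start, w$end)  # 689, 875
anchor_window <- function(segment, pos = nchar(segment), model, read_length) {
  l <- as.integer(read_length)
  start <- pos - l - model$delta_max
  end <- pos - model$delta_min
  if (start < 0 || pos > nchar(segment)) {
    abort(sprintf(
      "anchor window [%d, %d) is not fully determined; extension needs a known flank of at least l + delta_max = %d bp",
      start, end, as.integer(l + model$delta_max)))
  }
  list(start = as.integer(start), end = as.integer(end),
       sequence = substr(segment, start + 1L, end))
}

#' Overlap length and vote of a candidate extending mate
#'
#' Finds the largest `ext` in `(kappa, l)` such that the mate's length-`ext`
#' prefix aligns to the segment's length-`ext` suffix with mismatch fraction
#' at most `1 - tau`; the mate's base at index `ext` is its vote for the
#' next position. Overlaps of `kappa` or less are rejected as uninformative.
#'
#' @param mate candidate extending mate sequence (length l).
#' @param segment known segment the mate would extend.
#' @param params an [align_params()].
#' @return list with `ext` (0 on rejection) and `vote` (`NA` on rejection).
#' @export
compute_ext <- function(mate, segment, params = align_params()) {
  res <- .compute_ext_cpp(toupper(mate), toupper(segment),
                          as.integer(params$kappa), params$tau)
  if (res$ext == 0) {
    list(ext = 0L, vote = NA_character_)
  } else {
    list(ext = res$ext, vote = res$vote)
  }
}

#' Covering set for the segment frontier
#'
#' Reads qualified to vote on the next base: pairs with one mate anchored
#' (whole-mate match, budget `d`) in the anchor window whose opposite mate
#' passes the extension test in either orientation. Both orientations are
#' tested and the one with the larger overlap kept.
#'
#' @param segment known segment sequence; the frontier is its end.
#' @param index a `read_index` over the insertion read set.
#' @param params an [align_params()].
#' @param model an [insert_size_model()].
#' @return tibble with `pair` (index into the indexed set), `ext_mate`,
#'   `orientation`, `ext`, `vote`.
#' @export
covering_set <- function(segment, index, params = align_params(), model) {
  stopifnot(inherits(index, "read_index"))
  if (index$n_pairs == 0) {
    return(tibble::tibble(pair = integer(0), ext_mate = integer(0),
                          orientation = character(0), ext = integer(0),
                          vote = character(0)))
  }
  # validates the known flank and raises the state error if too short
  anchor_window(segment, nchar(segment), model, index$l)
  cs <- .covering_set_cpp(index$ptr, index$l, toupper(segment),
                          as.integer(model$delta_min), as.integer(model$delta_max),
                          as.integer(params$kappa), params$d, params$tau)
  tibble::tibble(pair = cs$pair, ext_mate = cs$ext_mate,
                 orientation = ifelse(cs$orient == 0L, "fwd", "rc"),
                 ext = cs$ext, vote = as.character(cs$vote))
}

#' One consensus decision from covering-set votes
#'
#' If two or more bases reach support fraction `eps_branch`, each backed by
#' at least `branch_min_reads` reads, the column is a divergence and the
#' supported bases are returned for branching. Otherwise the leading base is
#' called when it reaches `eps`, or when at most one vote dissents (a lone
#' dissenting vote on a thin column is read-error noise, not a haplotype).
#' Failing both, consensus is insufficient and extension terminates
#' (including for an empty covering set).
#'
#' @param votes character vector of per-read votes (bases).
#' @param params an [align_params()].
#' @return list with `action` (`"call"`, `"divergence"`, `"terminate"`) and
#'   `bases` (the called base, or the branch bases ordered by support).
#' @export
#' @examples
#' consensus_step(rep("C", 7))          # call C
#' consensus_step(character(0))         # terminate
#' consensus_step(c(rep("A", 10), rep("G", 9)),
#'                align_params(eps_branch = 0.4))  # divergence A, G
consensus_step <- function(votes, params = align_params()) {
  n <- length(votes)
  if (n == 0) return(list(action = "terminate", bases = character(0)))
  cnt <- table(factor(votes, levels = c("A", "C", "G", "T")))
  frac <- as.numeric(cnt) / n
  ord <- order(-as.numeric(cnt), names(cnt))
  branchy <- which(frac >= params$eps_branch - 1e-9 & as.numeric(cnt) > 0)
  called <- which(frac >= params$eps - 1e-9 & as.numeric(cnt) > 0)
  second <- as.numeric(cnt)[ord[2]]
  if (length(branchy) >= 2 && second >= params$branch_min_reads) {
    bases <- names(cnt)[ord][names(cnt)[ord] %in% names(cnt)[branchy]]
    list(action = "divergence", bases = bases)
  } else if (length(called) == 1 || n - as.numeric(cnt)[ord[1]] <= 1) {
    list(action = "call", bases = names(cnt)[ord[1]])
  } else {
    list(action = "terminate", bases = character(0))
  }
}

#' Extend a segment endpoint into the adjacent insertion
#'
#' Iteratively applies covering-set construction and consensus calling at
#' the segment frontier, appending called bases, forking on divergences
#' (depth-first, at most `max_branches` live hypotheses, with a global node
#' budget), and stopping each branch on insufficient consensus, the
#' extension cap, or successful overlap with the opposite segment's head
#' (tail of the extension matching `opposite_head` over `l` bases under the
#' mismatch-fraction threshold). The reverse direction is implemented by
#' reverse-complementing the segment, extending forward, and
#' reverse-complementing the result; `opposite_head` must then be given on
#' the reverse-complement strand as well.
#'
#' @param segment the known flank to extend (its 3' end is the frontier in
#'   the forward direction).
#' @param direction `"forward"` or `"reverse"`.
#' @param index a `read_index` over the insertion read set.
#' @param params an [align_params()].
#' @param model an [insert_size_model()].
#' @param opposite_head prefix of the opposite flank used for the
#'   successful-termination test (on the forward strand of the direction of
#'   travel); `""` disables the test.
#' @return list of hypotheses, each a list with `sequence` (appended bases,
#'   in the orientation of `segment`), `reason` (`"flank_overlap"`,
#'   `"no_consensus"`, `"max_extension"`, `"budget"`), `consumed`
#'   (pair indices whose votes were used), `support` (covering-set size per
#'   appended position), `path` (branch decisions).
#' @export
extend_segment <- function(segment, direction = c("forward", "reverse"),
                           index, params = align_params(), model,
                           opposite_head = "") {
  direction <- match.arg(direction)
  stopifnot(inherits(index, "read_index"))
  l <- index$l
  if (nchar(segment) < l + model$delta_max) {
    abort(sprintf("known flank (%d bp) shorter than l + delta_max (%d bp)",
                  nchar(segment), as.integer(l + model$delta_max)))
  }
  base <- if (direction == "forward") toupper(segment) else revcomp(segment)
  opp <- toupper(opposite_head)
  if (index$n_pairs == 0) {
    return(list(list(sequence = "", reason = "no_consensus",
                     consumed = integer(0), support = integer(0), path = "")))
  }
  hyps <- .extend_segment_cpp(
    index$ptr, l, base, opp,
    as.integer(model$delta_min), as.integer(model$delta_max),
    as.integer(params$kappa), params$d, params$tau,
    params$eps, params$eps_branch, params$branch_min_reads,
    params$max_branches, params$max_extension, params$node_budget)
  lapply(hyps, function(h) {
    seq <- if (direction == "forward") h$sequence else revcomp(h$sequence)
    sup <- if (direction == "forward") h$support else rev(h$support)
    list(sequence = seq, reason = h$reason, consumed = h$consumed + 1L,
         support = sup, path = h$path)
  })
}

#' Select the hypothesis accounting for the most reads
#'
#' A pair is accounted by a hypothesis if at least one of its mates matches
#' the hypothesis sequence (including its flank junctions) at some offset
#' within the anchored-search mismatch budget. The hypothesis accounting
#' for the greatest number of insertion-read-set pairs wins; ties break
#' deterministically to the first hypothesis in branch order.
#'
#' @param hypotheses list of hypotheses from [extend_segment()].
#' @param index the `read_index` the extension used.
#' @param params an [align_params()].
#' @param flank_left,flank_right reference flanks joined to the hypothesis
#'   sequence before matching, so junction-spanning reads count.
#' @return the winning hypothesis, with `accounted_read_count` added. A
#'   single hypothesis is returned unchanged, with the reads whose votes it
#'   consumed as its accounted count (no competition to resolve).
#' @export
score_and_select <- function(hypotheses, index, params = align_params(),
                             flank_left = "", flank_right = "") {
  if (length(hypotheses) == 0) {
    abort("no hypotheses to select from: extension failed for this insertion")
  }
  if (length(hypotheses) == 1) {
    out <- hypotheses[[1]]
    out$accounted_read_count <- length(out$consumed)
    out$n_hypotheses <- 1L
    return(out)
  }
  l <- index$l
  lf <- if (nchar(flank_left) > 0) substr(flank_left,
                                          max(1L, nchar(flank_left) - l + 2L),
                                          nchar(flank_left)) else ""
  rf <- if (nchar(flank_right) > 0) substr(flank_right, 1L,
                                           min(nchar(flank_right), l - 1L)) else ""
  seqs <- vapply(hypotheses, `[[`, "", "sequence")
  first_of <- match(seqs, seqs)   # identical sequences share one search
  counts <- integer(length(hypotheses))
  for (i in seq_along(hypotheses)) {
    if (first_of[i] != i) {
      counts[i] <- counts[first_of[i]]
      next
    }
    probe <- paste0(lf, seqs[i], rf)
    counts[i] <- if (nchar(seqs[i]) == 0 || nchar(probe) < l) 0L else {
      hits <- find_anchored(index, probe, d = params$d)
      length(unique(hits$pair))
    }
  }
  best <- which.max(counts)  # ties: first in branch order
  out <- hypotheses[[best]]
  out$accounted_read_count <- counts[best]
  out$n_hypotheses <- length(hypotheses)
  out
}
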