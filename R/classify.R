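#' Classify read pairs by mapping signature
#'
#' Each pair receives exactly one of four labels: `ORPHAN` (neither mate
#' maps), `OEA` (exactly one mate maps), `CONCORDANT` (some pair of mapping
#' locations has opposite strands in forward/reverse orientation with outer
#' fragment span inside `[delta_min, delta_max]`), else `DISCORDANT`.
#' Concordance quantifies existentially over the cross-product of the two
#' mates' location sets, so a single concordant placement suffices.
#' Over-coverage is a separate flag on concordant pairs, assigned by
#' [select_over_coverage()].
#'
#' @param mapping a `mapping_table` from [map_reads()] or [load_sam()].
#' @param model an [insert_size_model()].
#' @return tibble with `pair_id` and `label` (factor with levels
#'   ORPHAN, OEA, CONCORDANT, DISCORDANT).
#' @export
classify_pairs <- function(mapping, model) {
  stopifnot(inherits(mapping, "mapping_table"), inherits(model, "insert_size_model"))
  n <- attr(mapping, "n_pairs")
  l <- attr(mapping, "read_length")
  lab <- .classify_pairs_cpp(n, mapping$pair_id, mapping$mate, mapping$pos,
                             mapping$strand, l, model$delta_min, model$delta_max)
  tibble::tibble(
    pair_id = seq_len(n),
    label = factor(c("ORPHAN", "OEA", "CONCORDANT", "DISCORDANT")[lab + 1L],
                   levels = c("ORPHAN", "OEA", "CONCORDANT", "DISCORDANT"))
  )
}

#' Classify a single read pair from its per-mate location sets
#'
#' Convenience single-pair form of [classify_pairs()]; location tibbles use
#' `pos` (0-based) and `strand` (0 forward, 1 reverse, or "+"/"-").
#'
#' @param loc1,loc2 per-mate location tibbles (possibly zero-row).
#' @param model an [insert_size_model()].
#' @param read_length mate length l.
#' @return one of "ORPHAN", "OEA", "CONCORDANT", "DISCORDANT".
#' @export
#' @examples
#' m <- insert_size_model(200, 25)
#' classify_pair(tibble::tibble(pos = 100, strand = 0),
#'               tibble::tibble(pos = 264, strand = 1), m, 36)
classify_pair <- function(loc1, loc2, model, read_length) {
  norm <- function(x) {
    if (nrow(x) == 0) return(x)
    if (is.character(x$strand)) x$strand <- ifelse(x$strand == "-", 1L, 0L)
    x
  }
  loc1 <- norm(loc1)
  loc2 <- norm(loc2)
  tbl <- dplyr::bind_rows(
    if (nrow(loc1)) tibble::tibble(pair_id = 1L, mate = 1L, pos = loc1$pos,
                                   strand = loc1$strand),
    if (nrow(loc2)) tibble::tibble(pair_id = 1L, mate = 2L, pos = loc2$pos,
                                   strand = loc2$strand)
  )
  if (is.null(tbl) || nrow(tbl) == 0) {
    tbl <- tibble::tibble(pair_id = integer(0), mate = integer(0),
                          pos = integer(0), strand = integer(0))
  }
  lab <- .classify_pairs_cpp(1L, tbl$pair_id, tbl$mate, tbl$pos, tbl$strand,
                             as.integer(read_length),
                             model$delta_min, model$delta_max)
  c("ORPHAN", "OEA", "CONCORDANT", "DISCORDANT")[lab + 1L]
}

#' Depth-of-coverage profile over the reference
#'
#' Each mapped mate contributes +1 at each of its `l` positions for exactly
#' one placement; multi-mapped mates have one placement chosen uniformly at
#' random (seeded by the caller's RNG). `mu_doc` is the mean depth over
#' covered positions (depth > 0), so unsequenced gaps do not deflate the
#' genome mean. `mu_doc_pair` is, per pair, the mean of the two mates'
#' mean depths over the positions each covers.
#'
#' @param mapping a `mapping_table`.
#' @param reference_length reference length in bp.
#' @return object of class `coverage_profile`: list with `depth` (integer
#'   vector), `mu_doc`, `mu_doc_pair` (per-pair, NA when unmapped).
#' @export
compute_coverage <- function(mapping, reference_length = attr(mapping, "reference_length")) {
  l <- attr(mapping, "read_length")
  n <- attr(mapping, "n_pairs")
  # one placement per mapped mate, uniform among its hits
  key <- mapping$pair_id * 2L + mapping$mate
  ord <- order(key, runif(nrow(mapping)))
  pick <- ord[!duplicated(key[ord])]
  place <- mapping[pick, ]
  starts <- tabulate(place$pos + 1L, nbins = reference_length)
  ends <- tabulate(pmin(place$pos + l, reference_length) + 1L,
                   nbins = reference_length + 1L)
  depth <- cumsum(starts - ends[seq_len(reference_length)])
  # cumulative depth for O(1) per-read means
  cum <- c(0, cumsum(as.numeric(depth)))
  span_end <- pmin(place$pos + l, reference_length)
  mate_mean <- (cum[span_end + 1L] - cum[place$pos + 1L]) / (span_end - place$pos)
  acc <- matrix(NA_real_, n, 2)
  acc[cbind(place$pair_id, place$mate)] <- mate_mean
  mu_doc_pair <- rowMeans(acc, na.rm = TRUE)
  mu_doc_pair[is.nan(mu_doc_pair)] <- NA_real_
  structure(
    list(depth = depth, mu_doc = mean(depth[depth > 0]),
         mu_doc_pair = mu_doc_pair, read_length = l),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d bp, mean depth over covered positions %.2f\n",
              length(x$depth), x$mu_doc))
  invisible(x)
}

#' Probabilistic over-coverage selection for concordant pairs
#'
#' A concordant pair in a region of mean depth `mu_doc_pair` is admitted to
#' the insertion read set with probability
#' `max(0, 1 - mu_doc / mu_doc_pair)`: in a region at twice the genome mean,
#' half the reads are presumed to originate from a copied insertion
#' elsewhere in the donor. Draws come from the caller's RNG stream.
#'
#' @param labels classification tibble from [classify_pairs()].
#' @param profile a `coverage_profile` from [compute_coverage()].
#' @return logical vector over pairs: TRUE marks a concordant pair flagged
#'   OVER_COVERAGE.
#' @export
select_over_coverage <- function(labels, profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (!is.finite(profile$mu_doc) || profile$mu_doc <= 0) {
    abort("coverage profile has no covered positions; compute_coverage first")
  }
  p <- pmax(0, 1 - profile$mu_doc / profile$mu_doc_pair)
  p[is.na(p)] <- 0
  draw <- runif(length(p)) < p
  draw & labels$label == "CONCORDANT"
}

#' Build the insertion read set
#'
#' The union of pairs satisfying any of the four predicates: one-end
#' anchored, orphan, discordant, or probabilistically selected
#' over-coverage. Membership records which predicate(s) fired.
#'
#' @param reads read table (`read_id`, `seq1`, `seq2`).
#' @param labels classification tibble from [classify_pairs()].
#' @param over logical over-coverage flags from [select_over_coverage()].
#' @return an `insertion_read_set`: tibble with `pair_id`, `read_id`,
#'   `seq1`, `seq2`, predicate flags and the triggering `label`.
#' @export
build_irs <- function(reads, labels, over = rep(FALSE, nrow(labels))) {
  member <- labels$label %in% c("OEA", "ORPHAN", "DISCORDANT") | over
  idx <- which(member)
  out <- tibble::tibble(
    pair_id = idx,
    read_id = reads$read_id[idx],
    seq1 = reads$seq1[idx],
    seq2 = reads$seq2[idx],
    is_oea = labels$label[idx] == "OEA",
    is_orphan = labels$label[idx] == "ORPHAN",
    is_discordant = labels$label[idx] == "DISCORDANT",
    is_over_coverage = over[idx],
    label = ifelse(over[idx], "OVER_COVERAGE", as.character(labels$label[idx]))
  )
  structure(out, n_total_pairs = nrow(labels),
            class = c("insertion_read_set", class(out)))
}

#' Cluster one-end-anchored reads into candidate insertion loci
#'
#' Each OEA anchor implies a breakpoint interval `[pos + delta_min,
#' pos + delta_max]` downstream of a forward-strand anchor, or the mirrored
#' interval upstream of a reverse-strand anchor (measured from the anchor's
#' rightmost base). Mutually overlapping intervals merge into one cluster;
#' clusters below `min_support` anchors are dropped.
#'
#' @param mapping a `mapping_table`.
#' @param labels classification tibble from [classify_pairs()].
#' @param model an [insert_size_model()].
#' @param min_support minimum anchors per reported cluster.
#' @return tibble of BED-like records: `start`, `end` (0-based half-open),
#'   `n_reads`.
#' @export
cluster_oea <- function(mapping, labels, model, min_support = 4) {
  l <- attr(mapping, "read_length")
  oea <- labels$pair_id[labels$label == "OEA"]
  anchors <- mapping[mapping$pair_id %in% oea, ]
  if (nrow(anchors) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          n_reads = integer(0)))
  }
  lo <- ifelse(anchors$strand == 0L,
               anchors$pos + model$delta_min,
               anchors$pos + l - model$delta_max)
  hi <- ifelse(anchors$strand == 0L,
               anchors$pos + model$delta_max,
               anchors$pos + l - model$delta_min)
  ir <- IRanges::IRanges(start = pmax(0, round(lo)) + 1L, end = round(hi))
  merged <- IRanges::reduce(ir)
  ov <- IRanges::countOverlaps(merged, ir)
  keep <- ov >= min_support
  tibble::tibble(start = IRanges::start(merged)[keep] - 1L,
                 end = IRanges::end(merged)[keep],
                 n_reads = ov[keep])
}
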