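model36 <- insert_size_model(200, 25)

test_that("anchor window arithmetic follows [pos - l - dmax, pos - dmin)", {
  seg <- strrep("A", 1000)
  w <- anchor_window(seg, 1000, model36, 36)
  expect_equal(w$start, 689)
  expect_equal(w$end, 875)
  expect_equal(nchar(w$sequence), 186)
  # frontier exactly at the minimum known flank: window starts at offset 0
  seg2 <- strrep("C", 311)
  w2 <- anchor_window(seg2, 311, model36, 36)
  expect_equal(w2$start, 0)
  # any shorter flank is a state error
  expect_error(anchor_window(strrep("C", 310), 310, model36, 36),
               "not fully determined")
})

test_that("compute_ext finds the largest qualifying overlap and its vote", {
  p <- align_params(kappa = 5, tau = 0.9)
  seg <- paste0(strrep("G", 200), "ACGTACGTACGTACGTACGTACGTACGTAC")
  suffix30 <- substr(seg, nchar(seg) - 29, nchar(seg))
  mate <- paste0(suffix30, "TAACCG")        # 30 bp perfect overlap, l = 36
  res <- compute_ext(mate, seg, p)
  expect_equal(res$ext, 30)
  expect_equal(res$vote, "T")
  # one mismatch within the tau budget keeps the same ext
  mate_mm <- mate
  substr(mate_mm, 3, 3) <- ifelse(substr(mate_mm, 3, 3) == "A", "C", "A")
  res_mm <- compute_ext(mate_mm, seg, p)
  expect_equal(res_mm$ext, 30)
  expect_equal(res_mm$vote, "T")
  # overlap of kappa or less is rejected as uninformative
  res_short <- compute_ext(paste0(substr(seg, nchar(seg) - 4, nchar(seg)),
                                  strrep("T", 31)), seg, p)
  # a 5 bp suffix match alone cannot pass kappa = 5
  expect_true(res_short$ext == 0 || res_short$ext > 5)
})

test_that("consensus_step calls, branches, and terminates by the thresholds", {
  p <- align_params()
  expect_equal(consensus_step(rep("C", 7), p),
               list(action = "call", bases = "C"))
  expect_equal(consensus_step(character(0), p)$action, "terminate")
  div <- consensus_step(c(rep("A", 10), rep("G", 9)),
                        align_params(eps_branch = 0.4))
  expect_equal(div$action, "divergence")
  expect_equal(div$bases, c("A", "G"))
  # majority short of eps with no second branch-worthy base terminates
  expect_equal(consensus_step(c(rep("A", 6), "C", "G", "T", "T"), p)$action,
               "terminate")
  # deterministic base ordering on count ties
  tie <- consensus_step(c(rep("T", 5), rep("C", 5)),
                        align_params(eps_branch = 0.35))
  expect_equal(tie$bases, c("C", "T"))
})

test_that("covering_set matches the brute-force two-pass definition", {
  set.seed(602)
  for (rep in 1:8) {
    # small synthetic segment and read set built directly from it
    seg <- rand_dna(420)
    l <- 36
    n_signal <- 25
    irs <- tibble::tibble(pair_id = integer(0), seq1 = character(0),
                          seq2 = character(0))
    for (i in seq_len(n_signal)) {
      flen <- sample(125:275, 1)
      start <- sample(0:(420 - flen), 1)
      m1 <- substr(seg, start + 1, start + l)
      m2 <- revcomp(substr(seg, start + flen - l + 1, start + flen))
      if (runif(1) < 0.5) {
        irs <- dplyr::bind_rows(irs, tibble::tibble(pair_id = i, seq1 = m1, seq2 = m2))
      } else {
        irs <- dplyr::bind_rows(irs, tibble::tibble(pair_id = i, seq1 = m2, seq2 = m1))
      }
    }
    # plus random noise pairs
    for (i in 1:15) {
      irs <- dplyr::bind_rows(irs, tibble::tibble(
        pair_id = n_signal + i, seq1 = rand_dna(l), seq2 = rand_dna(l)))
    }
    irs$pair_id <- seq_len(nrow(irs))
    idx <- build_read_index(irs)
    p <- align_params(kappa = 6, d = 1)
    got <- covering_set(seg, idx, p, model36)
    exp <- oracle_covering_set(seg, irs, model36, l, kappa = 6, d = 1, tau = p$tau)
    got_key <- sort(paste(got$pair, got$ext_mate, got$ext, got$vote))
    exp_key <- sort(paste(exp$pair, exp$ext_mate, exp$ext, exp$vote))
    expect_identical(got_key, exp_key)
  }
})

test_that("covering_set is empty for an empty insertion read set", {
  empty <- build_read_index(tibble::tibble(pair_id = integer(0),
                                           seq1 = character(0),
                                           seq2 = character(0)))
  expect_equal(nrow(covering_set(rand_dna(400), empty, align_params(), model36)), 0)
})

test_that("the cached extension driver equals a stepwise covering/consensus loop", {
  # pure-R reference driver composed from the exported ops
  r_extend <- function(segment, index, params, model, opposite_head,
                       max_extension) {
    seq <- segment
    l <- index$l
    repeat {
      app <- nchar(seq) - nchar(segment)
      if (app >= max_extension) return(list(seq = seq, reason = "max_extension"))
      if (nchar(opposite_head) >= l && app >= l) {
        tail_l <- substr(seq, nchar(seq) - l + 1, nchar(seq))
        if (oracle_oplus(tail_l, substr(opposite_head, 1, l), params$tau)) {
          return(list(seq = seq, reason = "flank_overlap"))
        }
      }
      cs <- covering_set(seq, index, params, model)
      step <- consensus_step(cs$vote, params)
      if (step$action == "call") {
        seq <- paste0(seq, step$bases)
      } else if (step$action == "divergence") {
        seq <- paste0(seq, step$bases[1])  # follow the best-supported branch
      } else {
        return(list(seq = seq, reason = "no_consensus"))
      }
    }
  }
  sim <- tiny_sim(n_insertions = 1, reference_length = 4e4, insert_mean = 300,
                  seed = 67)
  set.seed(603)
  run <- assemble_from_reads(sim$reference, sim$reads, sim$loci,
                             model = model36)
  index <- build_read_index(run$irs)
  locus <- sim$loci[1]
  lf <- substr(sim$reference, locus - 599, locus)
  rf <- substr(sim$reference, locus + 1, locus + 600)
  params <- align_params(max_extension = 600)
  cpp <- extend_segment(lf, "forward", index, params, model36,
                        opposite_head = substr(rf, 1, 36))
  ref <- r_extend(lf, index, params, model36, substr(rf, 1, 36), 600)
  expect_equal(paste0(lf, cpp[[1]]$sequence), ref$seq)
  expect_equal(cpp[[1]]$reason, ref$reason)
})

test_that("an error-free unique insertion is reconstructed exactly", {
  sim <- tiny_sim(n_insertions = 1, reference_length = 5e4, insert_mean = 500,
                  seed = 7)
  set.seed(604)
  run <- assemble_from_reads(sim$reference, sim$reads, sim$loci,
                             model = model36,
                             params = align_params(max_extension = 1500))
  expect_equal(run$assembly$status, "merged")
  expect_equal(placement_distance(sim$truth$sequence[1],
                                  run$assembly$contig[1]), 0)
})

test_that("extension beyond a segment with no insertion terminates quickly", {
  sim <- tiny_sim(n_insertions = 0, reference_length = 4e4, seed = 71)
  set.seed(605)
  ref_idx <- build_reference_index(sim$reference)
  mapping <- map_reads(sim$reads, ref_idx, d = 2)
  labels <- classify_pairs(mapping, model36)
  prof <- compute_coverage(mapping, 4e4)
  irs <- build_irs(sim$reads, labels, select_over_coverage(labels, prof))
  index <- build_read_index(irs)
  mid <- 2e4
  seg <- substr(sim$reference, mid - 599, mid)
  hyps <- extend_segment(seg, "forward", index, align_params(), model36)
  for (h in hyps) {
    expect_equal(h$reason, "no_consensus")
    expect_lt(nchar(h$sequence), 3 * 36)
  }
})

test_that("near-identical planted repeats provoke divergence branching", {
  set.seed(606)
  # two copies of one template differing at a single internal base, planted
  # behind a shared unique flank: votes split at the divergent column
  l <- 36
  flank <- rand_dna(400)
  core <- rand_dna(120)
  alt <- core
  substr(alt, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                 substr(core, 60, 60))[1]
  mk_pairs <- function(hap, id0) {
    g <- paste0(flank, hap, rand_dna(400))
    out <- NULL
    for (s in seq(0, nchar(g) - 200, by = 4)) {
      m1 <- substr(g, s + 1, s + l)
      m2 <- revcomp(substr(g, s + 200 - l + 1, s + 200))
      out <- rbind(out, data.frame(seq1 = m1, seq2 = m2))
    }
    out
  }
  reads <- rbind(mk_pairs(core, 0), mk_pairs(alt, 1000))
  irs <- tibble::tibble(pair_id = seq_len(nrow(reads)),
                        seq1 = reads$seq1, seq2 = reads$seq2)
  idx <- build_read_index(irs)
  hyps <- extend_segment(flank, "forward", idx,
                         align_params(max_extension = 200), model36)
  expect_gte(length(hyps), 2)
})

test_that("hypothesis selection counts accounted reads and breaks ties first", {
  sim <- tiny_sim(n_insertions = 1, reference_length = 4e4, insert_mean = 400,
                  seed = 73)
  set.seed(607)
  run <- assemble_from_reads(sim$reference, sim$reads, sim$loci, model = model36)
  index <- build_read_index(run$irs)
  locus <- sim$loci[1]
  lf <- substr(sim$reference, locus - 599, locus)
  rf <- substr(sim$reference, locus + 1, locus + 600)
  truth <- sim$truth$sequence[1]
  full <- list(sequence = truth, reason = "flank_overlap",
               consumed = integer(0), support = integer(0), path = "")
  half <- list(sequence = substr(truth, 1, nchar(truth) %/% 2),
               reason = "no_consensus", consumed = integer(0),
               support = integer(0), path = "")
  pick <- score_and_select(list(half, full), index, align_params(),
                           flank_left = lf, flank_right = rf)
  expect_identical(pick$sequence, truth)
  expect_gt(pick$accounted_read_count, 0)
  expect_equal(pick$n_hypotheses, 2L)
  # identical hypotheses: the first in branch order wins
  h1 <- full
  h1$path <- "first"
  h2 <- full
  h2$path <- "second"
  tie <- score_and_select(list(h1, h2), index, align_params(),
                          flank_left = lf, flank_right = rf)
  expect_equal(tie$path, "first")
  # single hypothesis is returned unchanged
  single <- score_and_select(list(full), index)
  expect_identical(single$sequence, truth)
  expect_error(score_and_select(list(), index), "failed")
})

test_that("the reference-derived core is never rewritten by extension", {
  sim <- tiny_sim(n_insertions = 1, reference_length = 4e4, insert_mean = 300,
                  seed = 79)
  set.seed(608)
  run <- assemble_from_reads(sim$reference, sim$reads, sim$loci, model = model36)
  locus <- sim$loci[1]
  contig <- run$assembly$contig[1]
  flank <- substr(sim$reference, locus - 599, locus)
  expect_identical(substr(contig, 1, 600), flank)
})
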