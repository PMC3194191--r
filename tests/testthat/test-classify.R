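model36 <- insert_size_model(200, 25)

test_that("single-pair classification follows the label definitions", {
  loc <- function(pos, strand) tibble::tibble(pos = pos, strand = strand)
  none <- loc(integer(0), integer(0))
  # span 264 + 36 - 100 = 200, inside [125, 275], opposite strands
  expect_equal(classify_pair(loc(100, 0), loc(264, 1), model36, 36), "CONCORDANT")
  expect_equal(classify_pair(loc(100, 0), none, model36, 36), "OEA")
  expect_equal(classify_pair(none, none, model36, 36), "ORPHAN")
  expect_equal(classify_pair(loc(100, 0), loc(5100, 1), model36, 36), "DISCORDANT")
  # same strand is never concordant
  expect_equal(classify_pair(loc(100, 0), loc(264, 0), model36, 36), "DISCORDANT")
  # reverse mate left of the forward mate is not a proper fragment
  expect_equal(classify_pair(loc(264, 0), loc(100, 1), model36, 36), "DISCORDANT")
  # multi-mapping: one concordant placement suffices
  expect_equal(classify_pair(loc(c(100, 9000), c(0, 0)), loc(264, 1),
                             model36, 36), "CONCORDANT")
})

test_that("every pair gets exactly one of the four partition labels", {
  set.seed(77)
  sim <- tiny_sim(n_insertions = 2, reference_length = 6e4, insert_mean = 400,
                  coverage = 15, seed = 31)
  idx <- build_reference_index(sim$reference)
  mapping <- map_reads(sim$reads, idx, d = 2)
  labels <- classify_pairs(mapping, model36)
  expect_equal(nrow(labels), nrow(sim$reads))
  expect_false(anyNA(labels$label))
  # monotonicity: a wider concordance interval never turns CONCORDANT into DISCORDANT
  wide <- structure(list(mu = 200, sigma = 40, delta_min = 80, delta_max = 320),
                    class = "insert_size_model")
  labels2 <- classify_pairs(mapping, wide)
  was_conc <- labels$label == "CONCORDANT"
  expect_true(all(labels2$label[was_conc] == "CONCORDANT"))
})

test_that("coverage profile counts each placed mate once", {
  mk_mapping <- function(df, n_pairs, l = 36) {
    structure(df, read_length = l, d = 0, n_pairs = n_pairs,
              reference_length = 200L,
              class = c("mapping_table", class(df)))
  }
  one <- mk_mapping(tibble::tibble(pair_id = 1L, mate = 1L, pos = 0L,
                                   strand = 0L, nm = 0L), 1L)
  prof <- compute_coverage(one, 200)
  expect_equal(sum(prof$depth), 36)
  expect_true(all(prof$depth[1:36] == 1) && all(prof$depth[37:200] == 0))
  expect_equal(prof$mu_doc, 1)
  # duplicate reads at one locus double the per-read depth
  two <- mk_mapping(tibble::tibble(pair_id = c(1L, 2L), mate = c(1L, 1L),
                                   pos = c(0L, 0L), strand = c(0L, 0L),
                                   nm = c(0L, 0L)), 2L)
  prof2 <- compute_coverage(two, 200)
  expect_equal(prof2$mu_doc_pair[1], 2 * prof$mu_doc_pair[1])
})

test_that("uniform 40X simulation yields mean covered depth near 40", {
  sim <- tiny_sim(n_insertions = 0, reference_length = 1e5, coverage = 40,
                  seed = 41)
  idx <- build_reference_index(sim$reference)
  mapping <- map_reads(sim$reads, idx, d = 2)
  set.seed(1)
  prof <- compute_coverage(mapping, 1e5)
  expect_lt(abs(prof$mu_doc - 40), 1)
})

test_that("over-coverage admission follows max(0, 1 - mu/mu[r])", {
  n <- 30000
  labels <- tibble::tibble(pair_id = seq_len(n),
                           label = factor(rep("CONCORDANT", n),
                                          levels = c("ORPHAN", "OEA",
                                                     "CONCORDANT", "DISCORDANT")))
  prof3 <- structure(list(depth = rep(120L, 100), mu_doc = 40,
                          mu_doc_pair = rep(120, n), read_length = 36L),
                     class = "coverage_profile")
  set.seed(5)
  sel3 <- select_over_coverage(labels, prof3)
  # at 3x the mean, the admitted fraction is 2/3
  expect_lt(abs(mean(sel3) - 2 / 3), 0.01)
  prof2 <- structure(list(depth = rep(80L, 100), mu_doc = 40,
                          mu_doc_pair = rep(80, n), read_length = 36L),
                     class = "coverage_profile")
  set.seed(6)
  expect_lt(abs(mean(select_over_coverage(labels, prof2)) - 0.5), 0.01)
  # at or below the genome mean, nothing is admitted
  prof1 <- structure(list(depth = rep(40L, 100), mu_doc = 40,
                          mu_doc_pair = rep(39, n), read_length = 36L),
                     class = "coverage_profile")
  expect_false(any(select_over_coverage(labels, prof1)))
  bad <- structure(list(depth = integer(0), mu_doc = NaN,
                        mu_doc_pair = numeric(0)), class = "coverage_profile")
  expect_error(select_over_coverage(labels, bad), "covered")
})

test_that("the insertion read set is the union of the four predicates", {
  sim <- tiny_sim(n_insertions = 1, reference_length = 5e4, insert_mean = 600,
                  seed = 47)
  idx <- build_reference_index(sim$reference)
  mapping <- map_reads(sim$reads, idx, d = 2)
  labels <- classify_pairs(mapping, model36)
  set.seed(2)
  prof <- compute_coverage(mapping, 5e4)
  over <- select_over_coverage(labels, prof)
  irs <- build_irs(sim$reads, labels, over)
  expect_lte(nrow(irs), nrow(sim$reads))
  expect_true(all(irs$is_oea | irs$is_orphan | irs$is_discordant |
                    irs$is_over_coverage))
  # every pair with a mate strictly inside the unique insertion is present
  ft <- attr(sim$reads, "frag_truth")
  tr <- sim$truth
  m1_in <- ft$start >= tr$donor_locus & ft$start + 36 <= tr$donor_locus + tr$length
  m2s <- ft$start + ft$frag_len - 36
  m2_in <- m2s >= tr$donor_locus & m2s + 36 <= tr$donor_locus + tr$length
  expect_true(all(which(m1_in | m2_in) %in% irs$pair_id))
})

test_that("a donor equal to the reference yields no OEA or orphan members", {
  sim <- tiny_sim(n_insertions = 0, reference_length = 5e4, seed = 53)
  idx <- build_reference_index(sim$reference)
  mapping <- map_reads(sim$reads, idx, d = 2)
  labels <- classify_pairs(mapping, model36)
  set.seed(3)
  prof <- compute_coverage(mapping, 5e4)
  irs <- build_irs(sim$reads, labels, select_over_coverage(labels, prof))
  expect_equal(sum(irs$is_oea), 0)
  expect_equal(sum(irs$is_orphan), 0)
})

test_that("OEA clustering recovers planted loci", {
  sim <- tiny_sim(n_insertions = 2, reference_length = 8e4, insert_mean = 500,
                  seed = 59)
  idx <- build_reference_index(sim$reference)
  mapping <- map_reads(sim$reads, idx, d = 2)
  labels <- classify_pairs(mapping, model36)
  cl <- cluster_oea(mapping, labels, model36, min_support = 4)
  expect_equal(nrow(cl), 2)
  for (p in sim$loci) {
    expect_true(any(cl$start <= p & cl$end >= p))
  }
  # well-separated insertions give disjoint clusters
  expect_true(all(cl$start[-1] > cl$end[-nrow(cl)]))
  # no OEA reads, no loci
  none <- classify_pairs(mapping, model36)
  none$label[] <- "CONCORDANT"
  expect_equal(nrow(cluster_oea(mapping, none, model36)), 0)
})
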