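test_that("reference generation is deterministic and uniform", {
  a <- generate_reference(1000, seed = 1)
  b <- generate_reference(1000, seed = 1)
  expect_identical(a, b)
  expect_equal(nchar(a), 1000)
  expect_true(grepl("^[ACGT]+$", a))
  expect_true(generate_reference(1, seed = 0) %in% c("A", "C", "G", "T"))
  # per-base frequencies ~ 0.25 each at large n (binomial 99.99% CI ~ 0.25 +/- 0.0017)
  big <- generate_reference(1e6, seed = 7)
  freq <- table(strsplit(big, "", fixed = TRUE)[[1]]) / 1e6
  expect_true(all(abs(freq - 0.25) < 0.01))
  expect_error(generate_reference(0), "positive")
})

test_that("planting insertions preserves the reference on excision", {
  for (cat in c("case1_unique", "case2_copied", "case3_mixed")) {
    spec <- simulation_spec(reference_length = 2e5, n_insertions = 5,
                            category = cat, insert_size_mean = 800,
                            insert_size_sd = 80, seed = 3)
    ref <- generate_reference(spec$reference_length, seed = 3)
    pl <- plant_insertions(ref, spec)
    expect_equal(nchar(pl$donor), nchar(ref) + sum(pl$truth$length))
    expect_identical(excise_insertions(pl$donor, pl$truth), ref)
    expect_true(all(nchar(pl$truth$sequence) == pl$truth$length))
  }
})

test_that("zero insertions leave the reference untouched", {
  spec <- simulation_spec(reference_length = 5e4, n_insertions = 0, seed = 1)
  ref <- generate_reference(5e4, seed = 1)
  pl <- plant_insertions(ref, spec)
  expect_identical(pl$donor, ref)
  expect_equal(nrow(pl$truth), 0)
})

test_that("copied insertions occur at two or more donor positions", {
  spec <- simulation_spec(reference_length = 2e5, n_insertions = 4,
                          category = "case2_copied", insert_size_mean = 500,
                          insert_size_sd = 50, seed = 9)
  ref <- generate_reference(spec$reference_length, seed = 9)
  pl <- plant_insertions(ref, spec)
  for (i in seq_len(nrow(pl$truth))) {
    hits <- gregexpr(pl$truth$sequence[i], pl$donor, fixed = TRUE)[[1]]
    expect_gte(length(hits), 2)
  }
})

test_that("mixed insertions carry copied flanks around a unique core", {
  spec <- simulation_spec(reference_length = 2e5, n_insertions = 4,
                          category = "case3_mixed", insert_size_mean = 600,
                          insert_size_sd = 0, min_insert_size = 600, seed = 5)
  ref <- generate_reference(spec$reference_length, seed = 5)
  pl <- plant_insertions(ref, spec)
  for (i in seq_len(nrow(pl$truth))) {
    sq <- pl$truth$sequence[i]
    src <- pl$truth$copied_source_locus[i]
    hc <- pl$truth$length[i] %/% 2
    copied <- substr(ref, src + 1, src + hc)
    # copied content is split around the unique middle
    mid <- hc %/% 2
    expect_identical(substr(sq, 1, mid), substr(copied, 1, mid))
    expect_identical(substr(sq, nchar(sq) - (hc - mid) + 1, nchar(sq)),
                     substr(copied, mid + 1, hc))
    # the unique middle should not occur in the reference
    uniq <- substr(sq, mid + 1, mid + (pl$truth$length[i] - hc))
    expect_equal(gregexpr(uniq, ref, fixed = TRUE)[[1]][1], -1)
  }
})

test_that("planted insertion lengths follow the requested distribution", {
  spec <- simulation_spec(reference_length = 1e6, n_insertions = 10,
                          category = "case1_unique", seed = 21)
  ref <- generate_reference(spec$reference_length, seed = 21)
  pl <- plant_insertions(ref, spec)
  # mean of 10 draws from Normal(2000, 200): allow 3 standard errors
  expect_lt(abs(mean(pl$truth$length) - 2000), 3 * 200 / sqrt(10) + 1)
})

test_that("a too-short reference is refused with the spacing constraint named", {
  spec <- simulation_spec(reference_length = 2e4, n_insertions = 10,
                          category = "case1_unique", seed = 1)
  ref <- generate_reference(2e4, seed = 1)
  expect_error(plant_insertions(ref, spec), "spacing")
})

test_that("read sampling matches the coverage arithmetic and fragment model", {
  spec <- simulation_spec(reference_length = 1.8e5, n_insertions = 0,
                          coverage = 40, error_rate = 0, seed = 13)
  donor <- generate_reference(1.8e5, seed = 13)
  reads <- sample_reads(donor, spec)
  expect_equal(nrow(reads), round(40 * 1.8e5 / (2 * 36)))  # 100,000 pairs
  ft <- attr(reads, "frag_truth")
  # truncated-normal fragment mean: CLT bound at 100k pairs
  expect_lt(abs(mean(ft$frag_len) - 200), 1)
  expect_true(all(ft$frag_len >= 125 & ft$frag_len <= 275))
  # error-free: every mate is an exact substring of donor (spot-check 200)
  idx <- sample.int(nrow(reads), 200)
  for (i in idx) {
    expect_identical(substr(donor, ft$start[i] + 1, ft$start[i] + 36),
                     reads$seq1[i])
    expect_identical(
      revcomp(reads$seq2[i]),
      substr(donor, ft$start[i] + ft$frag_len[i] - 35,
             ft$start[i] + ft$frag_len[i]))
  }
  # coverage conservation: emitted bases / donor length = coverage +/- one pair
  expect_lt(abs(2 * 36 * nrow(reads) / nchar(donor) - 40), 2 * 36 / nchar(donor) + 1e-9)
})

test_that("identical specs give identical FASTQ output", {
  spec <- simulation_spec(reference_length = 3e4, n_insertions = 2,
                          insert_size_mean = 300, insert_size_sd = 30,
                          category = "case1_unique", seed = 5)
  s1 <- simulate_dataset(spec)
  s2 <- simulate_dataset(spec)
  expect_identical(s1$reads$seq1, s2$reads$seq1)
  expect_identical(s1$reads$seq2, s2$reads$seq2)
  expect_identical(s1$donor, s2$donor)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  expect_identical(readLines(file.path(d1, "reads_1.fastq")),
                   readLines(file.path(d2, "reads_1.fastq")))
})

test_that("substitution errors hit at the requested rate", {
  spec <- simulation_spec(reference_length = 1e5, n_insertions = 0,
                          error_rate = 0.01, seed = 17)
  donor <- generate_reference(1e5, seed = 17)
  reads <- sample_reads(donor, spec)
  ft <- attr(reads, "frag_truth")
  truth1 <- substring(donor, ft$start + 1, ft$start + 36)
  mm <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
               reads$seq1, truth1)
  rate <- sum(mm) / (36 * nrow(reads))
  expect_lt(abs(rate - 0.01), 0.002)
})

test_that("simulation artifacts round-trip through FASTQ and BED", {
  spec <- simulation_spec(reference_length = 3e4, n_insertions = 2,
                          insert_size_mean = 300, insert_size_sd = 30, seed = 8)
  sim <- simulate_dataset(spec)
  dir <- file.path(tempdir(), "simrt")
  write_simulation(sim, dir)
  back <- read_fastq_pair(file.path(dir, "reads_1.fastq"),
                          file.path(dir, "reads_2.fastq"))
  expect_identical(back$seq1, sim$reads$seq1)
  expect_identical(back$seq2, sim$reads$seq2)
  bed <- read_bed(file.path(dir, "loci.bed"))
  expect_equal(bed$start, sim$loci)
  fa <- read_fasta(file.path(dir, "reference.fa"))
  expect_identical(unname(fa[1]), sim$reference)
})
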