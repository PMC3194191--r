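# Independent oracles used across the suite. These are deliberately naive
# implementations (sliding scans, direct definition evaluation, quadratic DP)
# kept separate from the package's code paths.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# sliding-window Hamming scan; N never matches
oracle_scan <- function(text, pattern, d) {
  tc <- strsplit(text, "", fixed = TRUE)[[1]]
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(pc)
  n <- length(tc)
  pos <- integer(0)
  mm <- integer(0)
  if (m == 0 || m > n) return(list(pos = pos, mm = mm))
  for (s in 0:(n - m)) {
    w <- tc[(s + 1):(s + m)]
    x <- sum(w != pc | w == "N" | pc == "N")
    if (x <= d) {
      pos <- c(pos, s)
      mm <- c(mm, x)
    }
  }
  list(pos = as.integer(pos), mm = as.integer(mm))
}

# quadratic-DP Levenshtein, independent of utils::adist
oracle_levenshtein <- function(a, b) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(ac)
  n <- length(bc)
  dp <- matrix(0L, m + 1, n + 1)
  dp[, 1] <- 0:m
  dp[1, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      dp[i + 1, j + 1] <- min(dp[i, j] + (ac[i] != bc[j]),
                              dp[i, j + 1] + 1L,
                              dp[i + 1, j] + 1L)
    }
  }
  dp[m + 1, n + 1]
}

# ungapped comparison used by the assembler: mismatch fraction <= 1 - tau
oracle_oplus <- function(a, b, tau = 0.9) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  mm <- sum(ac != bc | ac == "N" | bc == "N")
  mm <= floor((1 - tau) * length(ac) + 1e-9)
}

# direct two-pass covering-set definition: anchored mate (whole-mate match
# with <= d substitutions, wholly inside the anchor window) and extending
# partner with the largest informative overlap passing the threshold
oracle_covering_set <- function(segment, irs, model, l,
                                kappa = 5, d = 2, tau = 0.9) {
  pos <- nchar(segment)
  wlo <- pos - l - model$delta_max
  whi <- pos - model$delta_min
  win <- substr(segment, wlo + 1, whi)
  out <- NULL
  for (i in seq_len(nrow(irs))) {
    mates <- list(irs$seq1[i], irs$seq2[i])
    for (am in 1:2) {
      anchored <- FALSE
      for (ao in c("fwd", "rc")) {
        a <- if (ao == "fwd") mates[[am]] else segext::revcomp(mates[[am]])
        sc <- oracle_scan(win, a, d)
        if (length(sc$pos) > 0) anchored <- TRUE
      }
      if (!anchored) next
      em <- 3 - am
      best_ext <- 0L
      best_vote <- NA_character_
      for (eo in c("fwd", "rc")) {
        p <- if (eo == "fwd") mates[[em]] else segext::revcomp(mates[[em]])
        for (ext in seq(l - 1, kappa + 1)) {
          pref <- substr(p, 1, ext)
          suf <- substr(segment, pos - ext + 1, pos)
          if (oracle_oplus(pref, suf, tau)) {
            if (ext > best_ext) {
              best_ext <- ext
              best_vote <- substr(p, ext + 1, ext + 1)
            }
            break
          }
        }
      }
      if (best_ext > 0) {
        out <- rbind(out, data.frame(pair = i, ext_mate = em,
                                     ext = best_ext, vote = best_vote))
      }
    }
  }
  if (is.null(out)) {
    data.frame(pair = integer(0), ext_mate = integer(0), ext = integer(0),
               vote = character(0))
  } else {
    # a pair may anchor with both mates; keep one row per (pair, ext_mate)
    out[!duplicated(out[, c("pair", "ext_mate")]), ]
  }
}

# small complete simulation bundle shared by several test files
tiny_sim <- function(n_insertions = 1, category = "case1_unique",
                     reference_length = 50000, insert_mean = 500,
                     insert_sd = 0, error_rate = 0, seed = 7,
                     coverage = 40) {
  spec <- simulation_spec(
    reference_length = reference_length, n_insertions = n_insertions,
    category = category, insert_size_mean = insert_mean,
    insert_size_sd = insert_sd, min_insert_size = min(insert_mean, 200),
    coverage = coverage, error_rate = error_rate, seed = seed)
  simulate_dataset(spec)
}
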