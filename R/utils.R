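#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors; delegates to
#' [Biostrings::reverseComplement()] so ambiguity codes are handled.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T%s}",
                  what, if (allow_n) ",N" else ""))
  }
  toupper(x)
}

# deterministic scoped seeding: functions taking `seed` leave the caller's
# RNG stream untouched
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

.stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}
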