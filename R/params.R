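#' Insert-size model for paired-end fragments
#'
#' Fragment (outer insert) lengths are modelled as Normal(mu, sigma) and
#' assumed to lie within three standard deviations of the mean, giving the
#' hard interval `[delta_min, delta_max] = [mu - 3 sigma, mu + 3 sigma]` used
#' by the concordance test and the anchor-window geometry.
#'
#' @param mu mean fragment length in bp.
#' @param sigma standard deviation of the fragment length in bp.
#' @return an object of class `insert_size_model` with fields `mu`, `sigma`,
#'   `delta_min`, `delta_max`.
#' @export
#' @examples
#' insert_size_model(200, 25)  # delta_min = 125, delta_max = 275
insert_size_model <- function(mu, sigma) {
  .stopifnot_scalar_count(mu, "mu")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    abort("`sigma` must be a single non-negative number")
  }
  dmin <- mu - 3 * sigma
  dmax <- mu + 3 * sigma
  if (dmin <= 0) abort("delta_min = mu - 3*sigma must be positive")
  structure(
    list(mu = mu, sigma = sigma, delta_min = dmin, delta_max = dmax),
    class = "insert_size_model"
  )
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf("<insert_size_model> mu = %g, sigma = %g, interval [%g, %g]\n",
              x$mu, x$sigma, x$delta_min, x$delta_max))
  invisible(x)
}

#' Alignment and extension parameters
#'
#' Tunables of the segment-extension assembler. The ungapped comparison
#' operator treats two strings as aligned when their mismatch fraction is at
#' most `1 - tau`. `kappa` is the shortest informative overlap between an
#' extending mate and the assembled suffix; `eps` is the consensus support
#' fraction required to call a base; `eps_branch` is the per-base support
#' fraction at which multiple bases trigger a divergence branch. `d` bounds
#' substitutions in the anchored whole-mate search.
#'
#' @param tau minimum identity fraction for the ungapped comparison, in (0,1].
#' @param kappa minimum informative overlap length, bp. The default (9)
#'   puts the chance of a random prefix/suffix agreement (about 4^-(kappa+1)
#'   per tested orientation) well below one spurious vote per assembled
#'   insertion at 40X candidate densities; shorter overlaps carry almost no
#'   signal and measurably corrupt thin consensus columns.
#' @param eps consensus support threshold, fraction of the covering set.
#' @param eps_branch divergence support threshold; must not exceed `eps`.
#'   A single threshold at or above 0.5 could never branch, hence the
#'   separate knob. The default (0.25) is deliberately below `1 - eps` so
#'   there is no dead zone: any column whose leading base falls short of
#'   `eps` still has a second base above `eps_branch` and branches instead
#'   of terminating outright.
#' @param branch_min_reads minimum reads behind the minority base for a
#'   column to count as a divergence; smaller splits are treated as
#'   read-error noise (the support threshold must be large enough to
#'   eliminate read errors, and a vote fraction alone cannot be on two- or
#'   three-read columns).
#' @param d mismatch budget of the anchored search (0..3).
#' @param max_branches beam width: maximum live hypotheses per endpoint.
#' @param max_extension safety cap on appended bases per endpoint; default
#'   covers twice the expected insertion length plus the anchor span.
#' @param node_budget total consensus columns explored per endpoint across
#'   all branches.
#' @return an object of class `align_params`.
#' @export
align_params <- function(tau = 0.9, kappa = 9, eps = 0.7, eps_branch = 0.25,
                         branch_min_reads = 3, d = 2, max_branches = 8,
                         max_extension = 2 * 2000 + 275,
                         node_budget = 2 * max_extension) {
  if (tau <= 0 || tau > 1) abort("`tau` must be in (0, 1]")
  if (eps <= 0 || eps > 1) abort("`eps` must be in (0, 1]")
  if (eps_branch <= 0 || eps_branch > eps) abort("`eps_branch` must be in (0, eps]")
  if (kappa < 1) abort("`kappa` must be >= 1")
  if (d < 0 || d > 3) abort("`d` must be between 0 and 3")
  if (max_branches < 1) abort("`max_branches` must be >= 1")
  if (branch_min_reads < 1) abort("`branch_min_reads` must be >= 1")
  structure(
    list(tau = tau, kappa = kappa, eps = eps, eps_branch = eps_branch,
         branch_min_reads = as.integer(branch_min_reads),
         d = as.integer(d), max_branches = as.integer(max_branches),
         max_extension = as.integer(max_extension),
         node_budget = as.numeric(node_budget)),
    class = "align_params"
  )
}

#' @export
print.align_params <- function(x, ...) {
  cat(sprintf(
    "<align_params> tau = %g, kappa = %d, eps = %g, eps_branch = %g, d = %d\n",
    x$tau, x$kappa, x$eps, x$eps_branch, x$d))
  cat(sprintf("  max_branches = %d, max_extension = %d, node_budget = %g\n",
              x$max_branches, x$max_extension, x$node_budget))
  invisible(x)
}

#' Simulation settings for planted-insertion experiments
#'
#' Captures the study conditions of the simulation protocol: insertions of
#' Normal(2000, 200) bp planted into a reference, 36 bp paired reads at 40X
#' with fragments Normal(200, 25) truncated to three standard deviations,
#' and a small per-base substitution error rate.
#'
#' @param reference_length reference length, bp.
#' @param n_insertions number of insertions to plant.
#' @param category one of `"case1_unique"`, `"case2_copied"`, `"case3_mixed"`.
#' @param insert_size_mean,insert_size_sd insertion length distribution, bp.
#' @param min_insert_size floor applied to drawn insertion lengths, bp.
#' @param coverage fold sequencing coverage of the donor.
#' @param read_length mate length `l`, bp.
#' @param frag_mean,frag_sd fragment (outer insert) length distribution, bp.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed for the whole simulation.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(reference_length = 1e6, n_insertions = 50,
                            category = c("case1_unique", "case2_copied", "case3_mixed"),
                            insert_size_mean = 2000, insert_size_sd = 200,
                            min_insert_size = 100,
                            coverage = 40, read_length = 36,
                            frag_mean = 200, frag_sd = 25,
                            error_rate = 0.001, seed = 1L) {
  category <- match.arg(category)
  for (nm in c("reference_length", "insert_size_mean", "coverage", "read_length",
               "frag_mean")) {
    .stopifnot_scalar_count(get(nm), nm)
  }
  if (n_insertions < 0) abort("`n_insertions` must be >= 0")
  if (error_rate < 0 || error_rate > 1) abort("`error_rate` must be in [0, 1]")
  if (frag_mean < 2 * read_length) {
    abort("`frag_mean` must be at least 2 * read_length so mates do not overlap")
  }
  structure(
    list(reference_length = as.integer(reference_length),
         n_insertions = as.integer(n_insertions), category = category,
         insert_size_mean = insert_size_mean, insert_size_sd = insert_size_sd,
         min_insert_size = as.integer(min_insert_size),
         coverage = coverage, read_length = as.integer(read_length),
         frag_mean = frag_mean, frag_sd = frag_sd,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %s: %d insertions (%g +/- %g bp) in %d bp reference\n",
    x$category, x$n_insertions, x$insert_size_mean, x$insert_size_sd,
    x$reference_length))
  cat(sprintf("  reads: %gX, l = %d, fragment %g +/- %g, error %g, seed %d\n",
              x$coverage, x$read_length, x$frag_mean, x$frag_sd,
              x$error_rate, x$seed))
  invisible(x)
}
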