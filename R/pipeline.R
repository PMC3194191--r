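#' Estimate the insert-size model from mapped concordant pairs
#'
#' Takes the outer fragment lengths of uniquely mapped pairs in proper
#' forward/reverse orientation, discards implausible spans (shorter than a
#' read or longer than three times the median, which removes discordant
#' placements without presupposing the model), and sets `mu` and `sigma`
#' to the sample mean and SD.
#'
#' @param mapping a `mapping_table`.
#' @param min_pairs minimum usable pairs; below this, explicit `mu` and
#'   `sigma` are required.
#' @param mu,sigma explicit values; when both are given estimation is
#'   skipped and the values echoed.
#' @return an [insert_size_model()].
#' @export
estimate_insert_model <- function(mapping, min_pairs = 1000, mu = NULL, sigma = NULL) {
  if (!is.null(mu) && !is.null(sigma)) {
    if (sigma == 0) {
      m <- structure(list(mu = mu, sigma = 0, delta_min = mu, delta_max = mu),
                     class = "insert_size_model")
      return(m)
    }
    return(insert_size_model(mu, sigma))
  }
  l <- attr(mapping, "read_length")
  key <- (mapping$pair_id - 1L) * 2L + mapping$mate  # mate slot per pair
  hits_per_slot <- tabulate(key, nbins = 2L * attr(mapping, "n_pairs"))
  both_unique <- hits_per_slot[c(TRUE, FALSE)] == 1L & hits_per_slot[c(FALSE, TRUE)] == 1L
  sel <- both_unique[mapping$pair_id]
  sub <- mapping[sel, ]
  # rows come sorted by (pair, mate): reshape two rows per pair
  m1 <- sub$mate == 1L
  p1 <- sub$pos[m1]; s1 <- sub$strand[m1]
  p2 <- sub$pos[!m1]; s2 <- sub$strand[!m1]
  proper <- s1 != s2
  fpos <- ifelse(s1 == 0L, p1, p2)
  rpos <- ifelse(s1 == 0L, p2, p1)
  span <- rpos + l - fpos
  span <- span[proper & rpos >= fpos]
  span <- span[span >= l & span <= 3 * median(span)]
  if (length(span) < min_pairs) {
    abort(sprintf(
      "only %d usable concordant pairs (< %d); supply explicit mu and sigma",
      length(span), min_pairs))
  }
  s <- sd(span)
  if (s == 0) {
    mu0 <- mean(span)
    return(structure(list(mu = mu0, sigma = 0, delta_min = mu0, delta_max = mu0),
                     class = "insert_size_model"))
  }
  insert_size_model(mean(span), s)
}

#' Assemble a run configuration
#'
#' Captures paths, parameters and the global seed for [run_pipeline()].
#' Every run writes a `config.txt` echo of all effective parameters.
#'
#' @param subcommand one of `"simulate"`, `"assemble"`, `"evaluate"`,
#'   `"all"`.
#' @param out_dir output directory.
#' @param reference,fastq1,fastq2,sam,bed,truth input paths as required by
#'   the subcommand.
#' @param sim a [simulation_spec()] for simulate mode.
#' @param params an [align_params()].
#' @param mu,sigma explicit insert-size parameters, or NULL to estimate.
#' @param d mapping mismatch budget.
#' @param threshold evaluation edit-distance margin, bp.
#' @param seed global seed; all randomness in the run flows from it.
#' @return a `run_config` list.
#' @export
run_config <- function(subcommand = c("all", "simulate", "assemble", "evaluate"),
                       out_dir, reference = NULL, fastq1 = NULL, fastq2 = NULL,
                       sam = NULL, bed = NULL, truth = NULL,
                       sim = simulation_spec(), params = align_params(),
                       mu = NULL, sigma = NULL, d = 2, threshold = 10,
                       seed = 1L) {
  structure(
    list(subcommand = match.arg(subcommand), out_dir = out_dir,
         reference = reference, fastq1 = fastq1, fastq2 = fastq2, sam = sam,
         bed = bed, truth = truth, sim = sim, params = params, mu = mu,
         sigma = sigma, d = d, threshold = threshold, seed = as.integer(seed)),
    class = "run_config"
  )
}

.echo_config <- function(config, path) {
  flat <- c(
    subcommand = config$subcommand, seed = config$seed, d = config$d,
    threshold = config$threshold,
    unlist(config$params), unlist(config$sim),
    mu = if (is.null(config$mu)) "estimate" else config$mu,
    sigma = if (is.null(config$sigma)) "estimate" else config$sigma)
  readr::write_lines(paste(names(flat), flat, sep = " = "), path)
}

#' Run the pipeline stages defined by a configuration
#'
#' `simulate` writes reference/donor FASTA, FASTQ pair, truth table and
#' loci BED into the output directory. `assemble` reads reference, FASTQ
#' pair and loci BED (or mappings from SAM), runs classification and
#' assembly, and writes `insertions.fa`, `contigs.fa`, `irs.tsv`,
#' `clusters.bed`, `assembly.tsv` and `mappings.sam`. `evaluate` compares
#' `assembly.tsv` to `truth.tsv` and writes `report.tsv` plus a
#' per-insertion `detail.tsv`. `all` chains the three. A `manifest.txt`
#' lists the artifacts of each stage.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the stage results (and the accuracy
#'   report for evaluate/all).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .echo_config(config, file.path(config$out_dir, "config.txt"))
  set.seed(config$seed)
  manifest <- character(0)
  res <- list()
  if (config$subcommand %in% c("simulate", "all")) {
    sim <- simulate_dataset(config$sim)
    files <- write_simulation(sim, config$out_dir)
    manifest <- c(manifest, files)
    res$sim <- sim
  }
  if (config$subcommand %in% c("assemble", "all")) {
    ref_path <- config$reference %||% file.path(config$out_dir, "reference.fa")
    bed_path <- config$bed %||% file.path(config$out_dir, "loci.bed")
    reference <- read_fasta(ref_path)[[1]]
    bed <- read_bed(bed_path)
    if (nrow(bed) == 0) {
      warning("no insertion loci in BED input; nothing to assemble")
      readr::write_lines(manifest, file.path(config$out_dir, "manifest.txt"))
      return(invisible(res))
    }
    f1 <- config$fastq1 %||% file.path(config$out_dir, "reads_1.fastq")
    f2 <- config$fastq2 %||% file.path(config$out_dir, "reads_2.fastq")
    reads <- read_fastq_pair(f1, f2)
    model <- if (!is.null(config$mu) && !is.null(config$sigma)) {
      insert_size_model(config$mu, config$sigma)
    } else NULL
    mapping <- if (!is.null(config$sam)) load_sam(config$sam, reads) else NULL
    run <- assemble_from_reads(reference, reads, bed$start, model = model,
                               params = config$params, d = config$d,
                               mapping = mapping)
    asm <- run$assembly
    readr::write_tsv(asm, file.path(config$out_dir, "assembly.tsv"))
    readr::write_tsv(tibble::as_tibble(run$irs),
                     file.path(config$out_dir, "irs.tsv"))
    keep <- !is.na(asm$contig)
    if (any(keep)) {
      write_fasta(setNames(asm$contig[keep], asm$insertion_id[keep]),
                  file.path(config$out_dir, "contigs.fa"))
    }
    ins_ok <- !is.na(asm$insertion) & nzchar(asm$insertion %||% "")
    if (any(ins_ok)) {
      write_fasta(setNames(asm$insertion[ins_ok], asm$insertion_id[ins_ok]),
                  file.path(config$out_dir, "insertions.fa"))
    }
    cl <- cluster_oea(run$mapping, run$labels, run$model)
    write_bed(tibble::tibble(chrom = "reference", cl),
              file.path(config$out_dir, "clusters.bed"))
    manifest <- c(manifest,
                  file.path(config$out_dir,
                            c("assembly.tsv", "irs.tsv", "contigs.fa",
                              "insertions.fa", "clusters.bed")))
    res$assembly <- asm
    res$model <- run$model
  }
  if (config$subcommand %in% c("evaluate", "all")) {
    truth_path <- config$truth %||% file.path(config$out_dir, "truth.tsv")
    truth <- readr::read_tsv(truth_path, show_col_types = FALSE)
    asm <- res$assembly %||%
      readr::read_tsv(file.path(config$out_dir, "assembly.tsv"),
                      show_col_types = FALSE)
    detail <- score_assembly(asm, truth, threshold = config$threshold)
    rep <- accuracy_report(
      tibble::tibble(replicate = 1L, n_insertions = nrow(detail),
                     n_correct = attr(detail, "n_correct"),
                     accuracy = attr(detail, "accuracy")),
      config = list(subcommand = config$subcommand, seed = config$seed,
                    threshold = config$threshold))
    readr::write_tsv(detail, file.path(config$out_dir, "detail.tsv"))
    readr::write_tsv(tidy(rep), file.path(config$out_dir, "report.tsv"))
    manifest <- c(manifest, file.path(config$out_dir,
                                      c("detail.tsv", "report.tsv")))
    res$report <- rep
  }
  readr::write_lines(manifest, file.path(config$out_dir, "manifest.txt"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
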