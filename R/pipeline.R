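#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis with the same defaults the
#' individual stages document, and validates inputs before any computation
#' runs (a missing file should fail fast, not mid-pipeline).
#'
#' @param genotype_csv path to a genotype CSV ([read_genotype_table()]), or
#'   `NULL` when starting from peaks.
#' @param peak_tsv path to a peak TSV ([read_peak_table()]), or `NULL`.
#' @param reference_csv optional genotype CSV of calibrator plants with known
#'   genotypes (needed for offset estimation when starting from peaks).
#' @param panel a `wdf_panel` (default [default_panel()]).
#' @param min_count consensus replica support (default: majority of replicas).
#' @param min_cotyped,metric distance stage settings.
#' @param method,scales,n_boot clustering/support stage settings.
#' @param theta,epsilon admixture stage settings.
#' @param seed non-negative integer seed.
#' @param outdir output directory (created if absent).
#' @return Object of class `wdf_config`.
#' @export
wdf_config <- function(genotype_csv = NULL, peak_tsv = NULL,
                       reference_csv = NULL, panel = default_panel(),
                       min_count = NULL, min_cotyped = 4L, metric = "dice",
                       method = "nj", scales = seq(0.5, 1.4, by = 0.1),
                       n_boot = 1000L, theta = 0.75, epsilon = 0.02,
                       seed = 1L, outdir = tempfile("wdf_run_")) {
  if (is.null(genotype_csv) && is.null(peak_tsv))
    stop("supply genotype_csv or peak_tsv")
  for (f in c(genotype_csv, peak_tsv, reference_csv))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L) stop("seed must be a non-negative integer")
  structure(list(genotype_csv = genotype_csv, peak_tsv = peak_tsv,
                 reference_csv = reference_csv, panel = panel,
                 min_count = min_count, min_cotyped = as.integer(min_cotyped),
                 metric = metric, method = method, scales = scales,
                 n_boot = as.integer(n_boot), theta = theta, epsilon = epsilon,
                 seed = seed, outdir = outdir),
            class = "wdf_config")
}

#' Run the full wine-fingerprinting analysis
#'
#' Orchestrates the stages end to end: (optional) consensus from peaks,
#' allele-sharing distances, tree with bootstrap support, candidate
#' assessment and main-variety assignment per wine, PCA ordination, panel PI.
#' Every intermediate artifact is written in a format the corresponding
#' reader accepts, so the pipeline is re-entrant at each stage, and the run
#' is a deterministic function of (inputs, config, seed). On failure all
#' partial outputs are removed.
#'
#' @param config a `wdf_config`.
#' @return Object of class `wdf_run`: list with `dataset`, `distances`,
#'   `tree`, `support`, `reports` (per wine), `ordination`, `pi`, `outdir`,
#'   `log`.
#' @export
run_wdf <- function(config) {
  stopifnot(inherits(config, "wdf_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  made <- character(0)
  log <- character(0)
  say <- function(stage, ...) {
    log <<- c(log, paste0("[", stage, "] ", paste0(..., collapse = "")))
  }
  out <- function(name) { p <- file.path(config$outdir, name); made <<- c(made, p); p }
  ok <- FALSE
  on.exit(if (!ok) unlink(made), add = TRUE)

  stage <- "input"
  res <- tryCatch({
    panel <- config$panel
    dataset <- NULL
    if (!is.null(config$genotype_csv)) {
      dataset <- read_genotype_table(config$genotype_csv, panel)
      say("input", "read ", length(dataset$varieties), " varieties, ",
          length(dataset$wines), " wines from ", config$genotype_csv)
    }
    if (!is.null(config$peak_tsv)) {
      stage <- "consensus"
      obs <- read_peak_table(config$peak_tsv, panel)
      say("consensus", "read ", length(obs), " replica observations")
      offsets <- NULL
      if (!is.null(config$reference_csv)) {
        refs <- read_genotype_table(config$reference_csv, panel)
        ref_ids <- names(refs$varieties)
        ref_obs <- Filter(function(o) o$sample_id %in% ref_ids, obs)
        if (length(ref_obs)) {
          offsets <- estimate_offsets(ref_obs, refs$varieties, panel)
          say("consensus", "calibrated ", sum(!offsets$uncalibrated),
              " loci against plant references")
        }
        obs <- Filter(function(o) !o$sample_id %in% ref_ids, obs)
        if (is.null(dataset))
          dataset <- wdf_dataset(panel, varieties = unname(refs$varieties))
      }
      by_sample <- split(obs, vapply(obs, `[[`, character(1), "sample_id"))
      wines <- lapply(by_sample, function(reps)
        consensus_profile(reps, panel, offsets, config$min_count))
      for (w in wines)
        say("consensus", w$id, ": ", length(w$calls), " loci typed, ",
            attr(w, "discards"), " peaks discarded")
      dataset <- wdf_dataset(panel,
                             varieties = unname(if (is.null(dataset)) list() else dataset$varieties),
                             wines = unname(wines), label = "run")
    }
    if (!length(dataset$wines)) stop("no wine profiles to analyse")
    write_genotype_table(dataset, out("genotypes.csv"))

    stage <- "distance"
    dmat <- distance_matrix(dataset, config$min_cotyped, config$metric)
    write_phylip(dmat, out("distances.phy"), csv = out("distances.csv"))
    say("distance", sum(!dmat$comparable[upper.tri(dmat$comparable)]),
        " incomparable pairs")

    stage <- "clustering"
    support <- NULL; tree <- NULL
    if (length(dataset_samples(dataset)) >= 3L) {
      support <- multiscale_bootstrap(dataset, method = config$method,
                                      scales = config$scales,
                                      n_boot = config$n_boot,
                                      min_cotyped = config$min_cotyped,
                                      metric = config$metric,
                                      seed = config$seed)
      support <- au_from_bp(support)
      tree <- support$tree
      writeLines(to_newick(tree), out("tree.nwk"))
      utils::write.csv(support$table, out("support.csv"), row.names = FALSE)
      clamp <- attr(tree, "clamped")
      if (!is.null(clamp) && clamp > 0)
        say("clustering", clamp, " negative branch length(s) clamped to zero")
      say("clustering", length(support$clusters), " clusters supported")
    }

    stage <- "admixture"
    ordination <- ordinate(dataset)
    pis <- panel_pi(dataset)
    candidates <- unname(dataset$varieties)
    reports <- list()
    rows <- list()
    for (w in dataset$wines) {
      if (!length(candidates)) break
      a <- assess_candidates(w, candidates, config$theta, config$min_cotyped,
                             config$metric)
      asg <- assign_main_variety(a, config$epsilon)
      reports[[w$id]] <- admixture_report(w, a, asg, tree = tree,
                                          support = support,
                                          ordination = ordination,
                                          panel_pi = pis)
      rows[[w$id]] <- as.data.frame(a)
      say("admixture", w$id, " -> ",
          if (asg$no_call) "no call" else asg$variety,
          if (isTRUE(asg$ambiguous)) " (ambiguous)" else "")
    }
    if (length(rows))
      utils::write.csv(do.call(rbind, rows), out("assessments.csv"),
                       row.names = FALSE)
    json <- vapply(reports, function(r) as.character(as_json(r)), character(1))
    writeLines(paste0("[", paste(json, collapse = ","), "]"),
               out("report.json"))
    writeLines(log, out("run.log"))
    list(dataset = dataset, distances = dmat, tree = tree, support = support,
         reports = reports, ordination = ordination, pi = pis,
         outdir = config$outdir, log = log)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  ok <- TRUE
  structure(res, class = "wdf_run")
}

#' @export
print.wdf_run <- function(x, ...) {
  cat("WDF pipeline run:", length(x$reports), "wine report(s) in", x$outdir, "\n")
  for (r in x$reports)
    print(structure(r$assignment, class = "wdf_assignment"))
  invisible(x)
}
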