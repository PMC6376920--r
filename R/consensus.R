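#' Size calibration against plant reference genotypes
#'
#' Capillary-electrophoresis sizing drifts between experiments, so plant
#' references with known genotypes are run alongside the wines as internal
#' calibrators. Each observed calibrator peak is matched to the nearest true
#' allele within one repeat unit; the per-locus additive offset is the median
#' of (true - observed) over matched peaks. The median resists a single
#' aberrant calibrator peak, and offsets are per locus because capillary
#' mobility varies with fragment size. Peaks that match no true allele are
#' ignored (calibrators can themselves carry artefacts). Loci with no matched
#' peak get offset 0 and are flagged `uncalibrated`; loci whose offset
#' magnitude reaches half a repeat unit are flagged `unreliable`, since
#' binning could then flip alleles to a neighbouring grid point.
#'
#' @param reference_obs list of `replica_observation` for the calibrator
#'   plants.
#' @param reference_truth list of `variety_genotype` with the calibrators'
#'   known calls (matched by sample id).
#' @param panel a `wdf_panel`.
#' @return Object of class `calibration_offsets`: a data frame with columns
#'   `locus`, `offset`, `n_peaks`, `uncalibrated`, `unreliable`.
#' @export
estimate_offsets <- function(reference_obs, reference_truth, panel) {
  if (!length(reference_obs)) stop("no reference observations supplied")
  truth <- stats::setNames(reference_truth,
                           vapply(reference_truth, `[[`, character(1), "id"))
  resid <- stats::setNames(vector("list", nrow(panel)), panel$name)
  for (obs in reference_obs) {
    g <- truth[[obs$sample_id]]
    if (is.null(g))
      stop("no known genotype for calibrator sample '", obs$sample_id, "'")
    for (locus in names(obs$peaks)) {
      true <- g$calls[[locus]]
      if (is.null(true)) next
      ru <- panel_locus(panel, locus)$repeat_unit
      sizes <- sort(obs$peaks[[locus]]$size)
      true_d <- sort(unique(true))
      if (length(sizes) == length(true_d)) {
        # complete calibrator call: pair peaks to alleles by rank, so a
        # uniform drift larger than one repeat unit is still measured (and
        # later flagged unreliable) instead of snapping to the wrong allele
        resid[[locus]] <- c(resid[[locus]], true_d - sizes)
      } else {
        for (size in sizes) {
          d <- true_d - size
          j <- which.min(abs(d))
          if (abs(d[[j]]) <= ru)  # unmatched peaks are artefacts, not evidence
            resid[[locus]] <- c(resid[[locus]], d[[j]])
        }
      }
    }
  }
  offset <- vapply(resid, function(r) if (length(r)) stats::median(r) else 0,
                   numeric(1))
  n_peaks <- vapply(resid, length, integer(1))
  out <- data.frame(
    locus = panel$name,
    offset = unname(offset),
    n_peaks = unname(n_peaks),
    uncalibrated = unname(n_peaks == 0L),
    unreliable = unname(abs(offset) >= panel$repeat_unit / 2),
    stringsAsFactors = FALSE
  )
  class(out) <- c("calibration_offsets", "data.frame")
  out
}

#' Bin a raw peak size to an integer allele
#'
#' Applies the locus calibration offset and rounds to the nearest integer bp
#' (halves away from zero). Sizes that land outside the locus plausibility
#' bounds are a bin error; the consensus stage discards such peaks and logs
#' them.
#'
#' @param raw_size fractional observed size in bp.
#' @param locus locus name.
#' @param panel a `wdf_panel`.
#' @param offsets a `calibration_offsets` (or `NULL` for no correction).
#' @return Integer allele size.
#' @export
bin_allele <- function(raw_size, locus, panel, offsets = NULL) {
  lr <- panel_locus(panel, locus)
  off <- 0
  if (!is.null(offsets)) {
    i <- match(locus, offsets$locus)
    if (!is.na(i)) off <- offsets$offset[[i]]
  }
  x <- raw_size + off
  a <- as.integer(sign(x) * floor(abs(x) + 0.5))  # round half away from zero
  if (any(a < lr$size_min | a > lr$size_max))
    stop("binned size ", paste(a, collapse = ", "), " outside bounds [",
         lr$size_min, ", ", lr$size_max, "] for locus ", locus)
  a
}

#' Consensus wine profile from technical replicas
#'
#' Validates alleles by recurrence across independent amplifications: after
#' calibration and binning, an allele enters the profile only if it occurs in
#' at least `min_count` distinct replicas. This is majority-vote consensus —
#' the standard forensic guard against both drop-in (a spurious allele rarely
#' recurs) and mis-sized one-off peaks. Loci where no allele reaches
#' `min_count` are left untyped. Out-of-bounds peaks are discarded and
#' reported in the `discards` attribute.
#'
#' @param replicas list of `replica_observation`, all for one sample
#'   (>= 2; wines are typed in at least 3 replicas, plants in 2 — 2 replicas
#'   are accepted with a warning).
#' @param panel a `wdf_panel`.
#' @param offsets optional `calibration_offsets`.
#' @param min_count minimum number of distinct replicas an allele must appear
#'   in (default `ceiling(n/2)`, i.e. 2 of 3; must be >= 2 and <= n).
#' @return A `wine_profile` whose `provenance` records, per typed locus, the
#'   replica support of each retained allele.
#' @export
consensus_profile <- function(replicas, panel, offsets = NULL, min_count = NULL) {
  if (length(replicas) < 2L)
    stop("consensus requires at least 2 replicas")
  ids <- unique(vapply(replicas, `[[`, character(1), "sample_id"))
  if (length(ids) != 1L)
    stop("replicas mix samples: ", paste(ids, collapse = ", "))
  n <- length(replicas)
  if (n == 2L)
    warning("only 2 replicas for '", ids, "'; wines should have at least 3")
  if (is.null(min_count) || !length(min_count))
    min_count <- max(2L, as.integer(ceiling(n / 2)))
  min_count <- as.integer(min_count)
  if (min_count < 2L) stop("min_count must be >= 2")
  if (min_count > n)
    stop("min_count (", min_count, ") exceeds the number of replicas (", n, ")")

  calls <- list(); provenance <- list(); discards <- 0L
  for (locus in panel$name) {
    seen <- lapply(replicas, function(obs) {
      pk <- obs$peaks[[locus]]
      if (is.null(pk) || !nrow(pk)) return(integer(0))
      binned <- integer(0)
      for (s in pk$size) {
        b <- tryCatch(bin_allele(s, locus, panel, offsets), error = function(e) NA_integer_)
        if (is.na(b)) discards <<- discards + 1L else binned <- c(binned, b)
      }
      unique(binned)  # within a replica an allele either recurs or not
    })
    support <- table(unlist(seen))
    keep <- as.integer(names(support))[support >= min_count]
    if (length(keep)) {
      calls[[locus]] <- sort(keep)
      provenance[[locus]] <- stats::setNames(
        as.integer(support[as.character(sort(keep))]), sort(keep))
    }
  }
  if (!length(calls))
    stop("no allele reached min_count = ", min_count, " at any locus for '",
         ids, "'")
  prof <- wine_profile(ids, calls, panel, provenance = provenance)
  attr(prof, "discards") <- discards
  attr(prof, "n_replicas") <- n
  attr(prof, "min_count") <- min_count
  prof
}
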