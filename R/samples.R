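#' Reference variety genotypes and wine profiles
#'
#' Two kinds of sample carry allele calls. A grapevine reference variety is
#' diploid: every typed locus holds exactly two integer allele sizes
#' (homozygotes repeat the allele). A wine is potentially a blend, so a typed
#' locus holds a *set* of validated allele sizes whose cardinality may exceed
#' two. Loci absent from `calls` are untyped.
#'
#' @param variety_id,wine_id sample name (non-empty character scalar).
#' @param calls named list, one element per typed locus: an integer vector of
#'   allele sizes in bp. Varieties require length-2 vectors; wines require
#'   non-empty vectors of distinct sizes.
#' @param panel optional `wdf_panel`; when supplied, calls are checked to
#'   reference panel loci and to lie within locus bounds.
#' @param provenance optional named integer vector: replica support per typed
#'   locus (how many technical replicas backed the call).
#' @param max_alleles cap on wine allele-set cardinality per locus (default 16,
#'   i.e. two alleles for each of up to 8 plausible blend components).
#'
#' @return `variety_genotype()` returns an object of class
#'   `c("variety_genotype", "wdf_sample")`; `wine_profile()` returns
#'   `c("wine_profile", "wdf_sample")`. Both are lists with elements `id` and
#'   `calls` (wines also carry `provenance`).
#' @examples
#' variety_genotype("Sangiovese", list(VVS2 = c(132L, 140L)))
#' wine_profile("Brunello_2014", list(VVS2 = c(132L, 134L, 140L)))
#' @name wdf_sample
NULL

#' @rdname wdf_sample
#' @export
variety_genotype <- function(variety_id, calls, panel = NULL) {
  check_sample_id(variety_id)
  calls <- normalize_calls(calls, panel)
  for (locus in names(calls)) {
    a <- calls[[locus]]
    if (length(a) != 2L)
      stop("variety '", variety_id, "', locus ", locus,
           ": a diploid reference call needs exactly 2 alleles, got ", length(a))
  }
  structure(list(id = variety_id, calls = calls),
            class = c("variety_genotype", "wdf_sample"))
}

#' @rdname wdf_sample
#' @export
wine_profile <- function(wine_id, calls, panel = NULL, provenance = NULL,
                         max_alleles = 16L) {
  check_sample_id(wine_id)
  calls <- normalize_calls(calls, panel)
  for (locus in names(calls)) {
    a <- unique(calls[[locus]])
    if (length(a) == 0L)
      stop("wine '", wine_id, "', locus ", locus, ": empty allele set")
    if (length(a) > max_alleles)
      stop("wine '", wine_id, "', locus ", locus, ": ", length(a),
           " alleles exceeds the blend cap of ", max_alleles)
    calls[[locus]] <- a
  }
  structure(list(id = wine_id, calls = calls, provenance = provenance),
            class = c("wine_profile", "wdf_sample"))
}

check_sample_id <- function(id) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sample id must be a non-empty character scalar")
  invisible(id)
}

# sort alleles, coerce to integer, optionally validate against a panel
normalize_calls <- function(calls, panel = NULL) {
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    stop("calls must be a named list keyed by locus name")
  if (anyDuplicated(names(calls)))
    stop("duplicate locus in calls: ",
         paste(unique(names(calls)[duplicated(names(calls))]), collapse = ", "))
  out <- lapply(calls, function(a) {
    a <- as.integer(a)
    if (anyNA(a)) stop("allele sizes must be integers")
    if (any(a < 1L)) stop("allele sizes must be >= 1 bp")
    sort(a)
  })
  if (!is.null(panel)) {
    unknown <- setdiff(names(out), panel$name)
    if (length(unknown))
      stop("calls reference loci not in the panel: ",
           paste(unknown, collapse = ", "))
    for (locus in names(out)) {
      lr <- panel_locus(panel, locus)
      a <- out[[locus]]
      if (any(a < lr$size_min | a > lr$size_max))
        stop("locus ", locus, ": allele outside plausibility bounds [",
             lr$size_min, ", ", lr$size_max, "]")
    }
  }
  out
}

#' Allele calls of a sample
#'
#' @param x a `wdf_sample`.
#' @param locus optional locus name; when given, the allele vector for that
#'   locus (or `NULL` if untyped).
#' @return Named list of allele vectors, or one allele vector.
#' @export
alleles <- function(x, locus = NULL) {
  stopifnot(inherits(x, "wdf_sample"))
  if (is.null(locus)) x$calls else x$calls[[locus]]
}

#' @export
print.wdf_sample <- function(x, ...) {
  kind <- if (inherits(x, "wine_profile")) "Wine profile" else "Variety genotype"
  cat(kind, " '", x$id, "' (", length(x$calls), " typed loci)\n", sep = "")
  for (locus in names(x$calls))
    cat("  ", format(locus, width = 10), paste(x$calls[[locus]], collapse = "/"), "\n")
  invisible(x)
}

#' Raw replicated peak observations
#'
#' One independent PCR amplification (technical replica) of one sample:
#' fractional peak sizes and fluorescence heights per marker, prior to any
#' calibration, binning or consensus validation.
#'
#' @param sample_id sample name.
#' @param replicate_index integer replica number (>= 1).
#' @param peaks named list keyed by marker: a data frame with numeric columns
#'   `size` (bp, fractional) and `height` (fluorescence units, positive).
#' @param panel optional `wdf_panel`; peaks outside locus plausibility bounds
#'   are retained but flagged in a logical column `out_of_bounds`.
#' @return Object of class `replica_observation`.
#' @export
replica_observation <- function(sample_id, replicate_index, peaks, panel = NULL) {
  check_sample_id(sample_id)
  replicate_index <- as.integer(replicate_index)
  if (is.na(replicate_index) || replicate_index < 1L)
    stop("replicate_index must be an integer >= 1")
  if (length(peaks) && (is.null(names(peaks)) || any(!nzchar(names(peaks)))))
    stop("peaks must be a named list keyed by marker")
  loci <- names(peaks)
  peaks <- lapply(loci, function(locus) {
    df <- as.data.frame(peaks[[locus]])
    if (!all(c("size", "height") %in% names(df)))
      stop("peaks for ", locus, " need 'size' and 'height' columns")
    if (any(df$size <= 0) || any(df$height <= 0))
      stop("peak sizes and heights must be positive")
    df$out_of_bounds <- if (is.null(panel)) rep(FALSE, nrow(df)) else {
      lr <- panel_locus(panel, locus)
      df$size < lr$size_min | df$size > lr$size_max
    }
    df[c("size", "height", "out_of_bounds")]
  })
  names(peaks) <- loci
  structure(list(sample_id = sample_id, replicate = replicate_index, peaks = peaks),
            class = "replica_observation")
}
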