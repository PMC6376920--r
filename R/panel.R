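#' SSR marker panels
#'
#' A panel is an ordered collection of microsatellite (SSR) loci, each with a
#' marker name, a repeat-unit length and plausibility bounds on amplified
#' fragment size (bp). Alleles are identified by integer fragment length after
#' binning; the bounds delimit what a credible peak can be for that marker.
#'
#' @param name character vector of marker names (unique, non-empty).
#' @param repeat_unit integer repeat-unit lengths in bp (recycled; default 2,
#'   the dinucleotide repeats typical of grapevine SSR panels).
#' @param size_min,size_max integer plausibility bounds in bp
#'   (`size_min < size_max`).
#'
#' @return An object of class `wdf_panel`: a data frame with columns
#'   `name`, `repeat_unit`, `size_min`, `size_max`, one row per locus.
#' @examples
#' wdf_panel(c("VVS2", "VVMD27"), size_min = c(120, 170), size_max = c(170, 220))
#' default_panel()
#' @export
wdf_panel <- function(name, repeat_unit = 2L, size_min = 80L, size_max = 400L) {
  name <- as.character(name)
  if (length(name) == 0L) stop("a panel needs at least one locus")
  if (anyDuplicated(name)) stop("duplicate locus names in panel: ",
                                paste(unique(name[duplicated(name)]), collapse = ", "))
  if (any(!nzchar(name))) stop("locus names must be non-empty")
  p <- data.frame(
    name        = name,
    repeat_unit = as.integer(rep_len(repeat_unit, length(name))),
    size_min    = as.integer(rep_len(size_min, length(name))),
    size_max    = as.integer(rep_len(size_max, length(name))),
    stringsAsFactors = FALSE
  )
  if (any(p$repeat_unit < 1L)) stop("repeat_unit must be >= 1")
  if (any(p$size_min >= p$size_max)) stop("size_min must be < size_max")
  class(p) <- c("wdf_panel", "data.frame")
  p
}

# single-row lookup; errors on unknown marker
#' @noRd
panel_locus <- function(panel, locus) {
  i <- match(locus, panel$name)
  if (is.na(i)) stop("locus '", locus, "' is not in the panel")
  panel[i, , drop = FALSE]
}

#' The nine-marker grapevine SSR panel used throughout
#'
#' Marker set commonly applied to wine varietal authentication:
#' VVMD21, VVMD25, VVMD27, VVMD32, VVMD34, VVS2, VrZag21, VrZag79, VrZag83.
#' Bounds are broad plausibility windows for amplified fragment sizes of these
#' dinucleotide markers; they reject gross sizing artefacts, not genotypes.
#'
#' @return A `wdf_panel` with nine loci.
#' @export
default_panel <- function() {
  wdf_panel(
    name = c("VVMD21", "VVMD25", "VVMD27", "VVMD32", "VVMD34",
             "VVS2", "VrZag21", "VrZag79", "VrZag83"),
    repeat_unit = 2L,
    size_min = c(230L, 230L, 170L, 230L, 230L, 120L, 180L, 230L, 180L),
    size_max = c(280L, 290L, 220L, 290L, 280L, 170L, 220L, 280L, 210L)
  )
}

#' @export
print.wdf_panel <- function(x, ...) {
  cat("SSR panel with", nrow(x), "loci:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
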