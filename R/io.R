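#' Read a genotype table
#'
#' Reads the flat CSV exchange format used throughout:
#' `sample_id,sample_type,locus,alleles` with `sample_type` one of `wine` or
#' `grapevine` and `alleles` a `/`-separated list of integer sizes in bp
#' (e.g. `150/152`). Grapevine rows must carry exactly two alleles (homozygote
#' written `150/150`); a grapevine sample may appear only once per locus.
#' Wine rows at the same locus are unioned, so a multi-row wine accumulates
#' its blend allele set. A blank `alleles` field marks the locus untyped and
#' the row is ignored. Rows naming loci absent from the panel are rejected.
#'
#' @param file path, connection, or a character vector of CSV lines.
#' @param panel a `wdf_panel`.
#' @param label dataset label.
#' @return A `wdf_dataset`.
#' @seealso [write_genotype_table()] for the inverse.
#' @export
read_genotype_table <- function(file, panel, label = "dataset") {
  lines <- read_lines_arg(file)
  if (!length(lines)) stop("empty genotype table")
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(header), c("sample_id", "sample_type", "locus", "alleles")))
    stop("genotype table header must be 'sample_id,sample_type,locus,alleles'")
  vg <- list(); wp <- list()
  for (i in seq_along(lines)[-1L]) {
    if (!nzchar(trimws(lines[[i]]))) next
    f <- trimws(strsplit(lines[[i]], ",", fixed = TRUE)[[1L]])
    if (length(f) < 3L || length(f) > 4L)
      stop("malformed genotype row at line ", i, ": ", lines[[i]])
    if (length(f) == 3L) f <- c(f, "")
    id <- f[[1L]]; type <- f[[2L]]; locus <- f[[3L]]; al <- f[[4L]]
    if (!type %in% c("wine", "grapevine"))
      stop("unknown sample_type '", type, "' at line ", i)
    if (!locus %in% panel$name)
      stop("line ", i, ": locus '", locus, "' is not in the panel")
    if (!nzchar(al)) next  # blank alleles = untyped locus
    sizes <- suppressWarnings(as.integer(strsplit(al, "/", fixed = TRUE)[[1L]]))
    if (anyNA(sizes))
      stop("malformed alleles field '", al, "' at line ", i)
    if (type == "grapevine") {
      if (length(sizes) != 2L)
        stop("line ", i, ": grapevine '", id, "' must have exactly 2 alleles at ",
             locus, ", got ", length(sizes))
      if (!is.null(vg[[id]][[locus]]))
        stop("duplicate grapevine call for ('", id, "', ", locus, ") at line ", i)
      vg[[id]][[locus]] <- sort(sizes)
    } else {
      wp[[id]][[locus]] <- sort(unique(c(wp[[id]][[locus]], sizes)))
    }
  }
  wdf_dataset(
    panel,
    varieties = lapply(names(vg), function(id) variety_genotype(id, vg[[id]], panel)),
    wines = lapply(names(wp), function(id) wine_profile(id, wp[[id]], panel)),
    label = label
  )
}

#' Write a genotype table
#'
#' Serializes a dataset to the CSV exchange format read by
#' [read_genotype_table()]; the round trip is the identity up to row order.
#' Loci are emitted in panel order, varieties before wines.
#'
#' @param dataset a `wdf_dataset`.
#' @param file optional path or connection; when `NULL` the CSV lines are
#'   returned as a character vector.
#' @return The CSV lines, invisibly when written to `file`.
#' @export
write_genotype_table <- function(dataset, file = NULL) {
  stopifnot(inherits(dataset, "wdf_dataset"))
  rows <- "sample_id,sample_type,locus,alleles"
  emit <- function(s, type) {
    for (locus in intersect(dataset$panel$name, names(s$calls)))
      rows[[length(rows) + 1L]] <<- paste(
        s$id, type, locus, paste(s$calls[[locus]], collapse = "/"), sep = ",")
  }
  for (s in dataset$varieties) emit(s, "grapevine")
  for (s in dataset$wines) emit(s, "wine")
  rows <- unlist(rows)
  if (is.null(file)) return(rows)
  writeLines(rows, file)
  invisible(rows)
}

#' Read a capillary-electrophoresis peak table
#'
#' Reads the generic fragment-analysis export format: tab-separated with
#' header `sample_id  replicate  marker  size  height`. Sizes are fractional
#' bp as scored by the fragment analyser; heights are positive fluorescence
#' units. Peaks are grouped by (sample, replicate); sizes outside the locus
#' plausibility bounds are retained but flagged so the consensus stage can
#' discard and log them.
#'
#' @param file path, connection, or character vector of TSV lines.
#' @param panel a `wdf_panel`.
#' @return List of `replica_observation`, ordered by first appearance.
#' @export
read_peak_table <- function(file, panel) {
  lines <- read_lines_arg(file)
  if (!length(lines)) stop("empty peak table")
  header <- trimws(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  if (!identical(header, c("sample_id", "replicate", "marker", "size", "height")))
    stop("peak table header must be 'sample_id\\treplicate\\tmarker\\tsize\\theight'")
  recs <- list()
  for (i in seq_along(lines)[-1L]) {
    if (!nzchar(trimws(lines[[i]]))) next
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(f) != 5L) stop("malformed peak row at line ", i)
    rep_num <- suppressWarnings(as.numeric(f[[2L]]))
    if (is.na(rep_num) || rep_num != round(rep_num))
      stop("non-integer replicate '", f[[2L]], "' at line ", i)
    size <- suppressWarnings(as.numeric(f[[4L]]))
    height <- suppressWarnings(as.numeric(f[[5L]]))
    if (is.na(size) || size <= 0) stop("non-positive size at line ", i)
    if (is.na(height) || height <= 0) stop("non-positive height at line ", i)
    if (!f[[3L]] %in% panel$name)
      stop("line ", i, ": marker '", f[[3L]], "' is not in the panel")
    key <- paste(f[[1L]], rep_num, sep = "\r")
    recs[[key]]$sample_id <- f[[1L]]
    recs[[key]]$replicate <- as.integer(rep_num)
    recs[[key]]$peaks[[f[[3L]]]] <-
      rbind(recs[[key]]$peaks[[f[[3L]]]],
            data.frame(size = size, height = height))
  }
  lapply(unname(recs), function(r)
    replica_observation(r$sample_id, r$replicate, r$peaks, panel))
}

#' Serialize a dataset to a single JSON document
#'
#' @param dataset a `wdf_dataset`.
#' @return A JSON string (panel, varieties, wines with per-locus calls).
#' @export
dataset_to_json <- function(dataset) {
  stopifnot(inherits(dataset, "wdf_dataset"))
  doc <- list(
    label = dataset$label,
    panel = as.data.frame(dataset$panel),
    varieties = lapply(dataset$varieties, function(s)
      list(id = s$id, calls = s$calls)),
    wines = lapply(dataset$wines, function(s)
      list(id = s$id, calls = s$calls))
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
}

# accept a path/connection or in-memory lines
#' @noRd
read_lines_arg <- function(file) {
  if (is.character(file) && length(file) == 1L && !grepl("\n", file) &&
      (file.exists(file) || grepl("^[a-zA-Z]+://", file)))
    return(readLines(file, warn = FALSE))
  if (inherits(file, "connection")) return(readLines(file, warn = FALSE))
  if (is.character(file)) return(unlist(strsplit(file, "\n", fixed = TRUE)))
  stop("'file' must be a path, connection, or character lines")
}
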