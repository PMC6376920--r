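#' Dataset of reference varieties and wine profiles
#'
#' Bundles a marker panel with the grapevine reference genotypes and validated
#' wine profiles typed on it. All sample ids must be unique across both sample
#' kinds and every call must reference a panel locus.
#'
#' @param panel a `wdf_panel`.
#' @param varieties list of `variety_genotype` objects.
#' @param wines list of `wine_profile` objects.
#' @param label dataset name (used in merged-databank bookkeeping).
#' @return Object of class `wdf_dataset`.
#' @export
wdf_dataset <- function(panel, varieties = list(), wines = list(), label = "dataset") {
  stopifnot(inherits(panel, "wdf_panel"))
  if (!all(vapply(varieties, inherits, logical(1), "variety_genotype")))
    stop("'varieties' must all be variety_genotype objects")
  if (!all(vapply(wines, inherits, logical(1), "wine_profile")))
    stop("'wines' must all be wine_profile objects")
  ids <- c(vapply(varieties, `[[`, character(1), "id"),
           vapply(wines, `[[`, character(1), "id"))
  if (anyDuplicated(ids))
    stop("duplicate sample ids in dataset: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (s in c(varieties, wines)) {
    unknown <- setdiff(names(s$calls), panel$name)
    if (length(unknown))
      stop("sample '", s$id, "' references loci not in the panel: ",
           paste(unknown, collapse = ", "))
  }
  names(varieties) <- vapply(varieties, `[[`, character(1), "id")
  names(wines) <- vapply(wines, `[[`, character(1), "id")
  structure(list(panel = panel, varieties = varieties, wines = wines,
                 label = as.character(label)),
            class = "wdf_dataset")
}

#' @export
print.wdf_dataset <- function(x, ...) {
  cat("WDF dataset '", x$label, "': ", length(x$varieties),
      " reference varieties, ", length(x$wines), " wines, ",
      nrow(x$panel), " SSR loci\n", sep = "")
  invisible(x)
}

# all samples of a dataset as one list (varieties first)
#' @noRd
dataset_samples <- function(dataset) c(dataset$varieties, dataset$wines)

#' Merge genotype datasets into a single databank
#'
#' Concatenates the samples of several datasets, as when independent typing
#' experiments are merged into one profiling databank. Duplicate sample ids
#' are allowed only when their calls agree exactly (then deduplicated);
#' conflicting duplicates are an error, never silently overwritten. The merged
#' panel is the union or the intersection of the input panels.
#'
#' @param datasets list of `wdf_dataset` objects (at least one).
#' @param policy `"union"` (default) or `"intersection"`: how panels combine.
#'   Calls at loci outside the merged panel are dropped.
#' @param label label of the merged dataset.
#' @return A `wdf_dataset`.
#' @export
merge_datasets <- function(datasets, policy = c("union", "intersection"),
                           label = "merged") {
  policy <- match.arg(policy)
  if (!length(datasets)) stop("merge_datasets needs at least one dataset")
  stopifnot(all(vapply(datasets, inherits, logical(1), "wdf_dataset")))
  panels <- lapply(datasets, `[[`, "panel")
  loci <- Reduce(if (policy == "union") union else intersect,
                 lapply(panels, `[[`, "name"))
  if (!length(loci)) stop("merged panel is empty under policy '", policy, "'")
  rows <- do.call(rbind, lapply(panels, as.data.frame))
  rows <- rows[!duplicated(rows$name), , drop = FALSE]
  rows <- rows[match(loci, rows$name), , drop = FALSE]
  # same marker typed with different repeat-unit conventions cannot be merged
  conv <- do.call(rbind, lapply(panels, as.data.frame))
  bad <- tapply(conv$repeat_unit, conv$name, function(u) length(unique(u)) > 1L)
  if (any(bad))
    stop("repeat-unit conventions disagree for loci: ",
         paste(names(bad)[bad], collapse = ", "))
  panel <- wdf_panel(rows$name, rows$repeat_unit, rows$size_min, rows$size_max)

  take <- function(kind) {
    pool <- list()
    for (d in datasets) for (s in d[[kind]]) {
      s$calls <- s$calls[intersect(names(s$calls), loci)]
      if (!is.null(pool[[s$id]])) {
        old <- pool[[s$id]]$calls
        if (!identical(old[order(names(old))], s$calls[order(names(s$calls))])) {
          all_loci <- union(names(old), names(s$calls))
          diff <- all_loci[!vapply(all_loci, function(l)
            identical(old[[l]], s$calls[[l]]), logical(1))]
          stop("conflicting duplicate sample '", s$id, "' at loci: ",
               paste(sort(diff), collapse = ", "))
        }
      } else pool[[s$id]] <- s
    }
    unname(pool)
  }
  wdf_dataset(panel, varieties = take("varieties"), wines = take("wines"),
              label = label)
}
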