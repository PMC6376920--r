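#' Allele-sharing similarity of one locus
#'
#' Dice coefficient on allele multisets: `2 * |a intersect b| / (|a| + |b|)`,
#' with the intersection counted with multiplicity. Wine allele sets carry
#' each validated size once; diploid reference calls keep both gene copies, so
#' for two diploid genotypes the measure reduces exactly to
#' `(shared allele copies) / 2` — the classical allele-sharing similarity.
#' Jaccard (`|a intersect b| / |a union b|` on distinct sizes) is available
#' as an alternative.
#'
#' @param a,b integer allele vectors (non-empty; repeats meaningful for
#'   `"dice"`).
#' @param metric `"dice"` (default) or `"jaccard"`.
#' @return Similarity in \[0, 1\].
#' @export
locus_similarity <- function(a, b, metric = c("dice", "jaccard")) {
  metric <- match.arg(metric)
  if (!length(a) || !length(b)) stop("allele sets must be non-empty")
  if (metric == "jaccard") {
    a <- unique(a); b <- unique(b)
    return(length(intersect(a, b)) / length(union(a, b)))
  }
  ta <- table(a); tb <- table(b)
  shared <- sum(pmin(ta[names(ta)], tb[names(ta)]), na.rm = TRUE)
  2 * shared / (length(a) + length(b))
}

#' Distance between two allele profiles
#'
#' One minus the mean locus similarity over loci typed in *both* profiles.
#' Pairs sharing fewer than `min_cotyped` typed loci carry too little common
#' evidence to compare: they are flagged incomparable and assigned the
#' maximal distance 1 so that tree building still receives a complete matrix,
#' while the comparability flag travels into reports.
#'
#' @param pa,pb `wdf_sample` objects (wine profiles or variety genotypes).
#' @param min_cotyped minimum co-typed loci for a meaningful comparison
#'   (default 4).
#' @param metric passed to [locus_similarity()].
#' @return List with `distance` in \[0, 1\], `comparable` flag, and `n_cotyped`.
#' @export
profile_distance <- function(pa, pb, min_cotyped = 4L,
                             metric = c("dice", "jaccard")) {
  metric <- match.arg(metric)
  shared <- intersect(names(pa$calls), names(pb$calls))
  n <- length(shared)
  if (n < min_cotyped)
    return(list(distance = 1, comparable = FALSE, n_cotyped = n))
  sims <- vapply(shared, function(l)
    locus_similarity(pa$calls[[l]], pb$calls[[l]], metric), numeric(1))
  list(distance = 1 - mean(sims), comparable = TRUE, n_cotyped = n)
}

#' Pairwise allele-sharing distance matrix
#'
#' @param profiles list of `wdf_sample` objects (>= 2) or a `wdf_dataset`
#'   (varieties then wines).
#' @param min_cotyped,metric passed to [profile_distance()].
#' @return Object of class `wdf_dist`: list with `labels`, `d` (symmetric
#'   numeric matrix, zero diagonal), `comparable` (logical matrix) and
#'   `n_cotyped` (integer matrix).
#' @export
distance_matrix <- function(profiles, min_cotyped = 4L,
                            metric = c("dice", "jaccard")) {
  metric <- match.arg(metric)
  if (inherits(profiles, "wdf_dataset")) profiles <- dataset_samples(profiles)
  n <- length(profiles)
  if (n < 2L) stop("distance_matrix needs at least 2 profiles")
  labels <- vapply(profiles, `[[`, character(1), "id")
  if (anyDuplicated(labels)) stop("duplicate profile ids")
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  comp <- matrix(TRUE, n, n, dimnames = dimnames(d))
  cot <- matrix(0L, n, n, dimnames = dimnames(d))
  diag(cot) <- vapply(profiles, function(p) length(p$calls), integer(1))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- profile_distance(profiles[[i]], profiles[[j]], min_cotyped, metric)
    d[i, j] <- d[j, i] <- r$distance
    comp[i, j] <- comp[j, i] <- r$comparable
    cot[i, j] <- cot[j, i] <- r$n_cotyped
  }
  structure(list(labels = labels, d = d, comparable = comp, n_cotyped = cot,
                 min_cotyped = as.integer(min_cotyped), metric = metric),
            class = "wdf_dist")
}

#' @export
as.matrix.wdf_dist <- function(x, ...) x$d

#' @export
as.dist.wdf_dist <- function(m, ...) stats::as.dist(m$d)

#' @export
print.wdf_dist <- function(x, ...) {
  cat("Allele-sharing distance matrix (", x$metric, ") over ",
      length(x$labels), " profiles\n", sep = "")
  if (any(!x$comparable))
    cat("  ", sum(!x$comparable[upper.tri(x$comparable)]),
        " pair(s) incomparable (< ", x$min_cotyped, " co-typed loci)\n", sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' Write a distance matrix in square PHYLIP format (plus CSV)
#'
#' @param x a `wdf_dist`.
#' @param file output path for the PHYLIP file; labels are truncated/padded
#'   to 10 characters as the classic format requires.
#' @param csv optional path for a labelled CSV copy.
#' @return `file`, invisibly.
#' @export
write_phylip <- function(x, file, csv = NULL) {
  stopifnot(inherits(x, "wdf_dist"))
  n <- length(x$labels)
  lab <- formatC(substr(gsub("\\s", "_", x$labels), 1, 10), width = -10)
  lines <- c(format(n),
             vapply(seq_len(n), function(i)
               paste0(lab[[i]], paste(sprintf("%.6f", x$d[i, ]), collapse = " ")),
               character(1)))
  writeLines(lines, file)
  if (!is.null(csv))
    utils::write.csv(as.data.frame(x$d), csv, row.names = TRUE)
  invisible(file)
}
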