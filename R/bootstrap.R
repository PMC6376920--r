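#' Multiscale bootstrap support for tree clusters
#'
#' Resamples the panel's loci — the exchangeable units of evidence in an SSR
#' study — with replacement at several sample-size scales, rebuilds the
#' distance matrix and tree for each replicate, and counts how often each
#' cluster (internal-edge bipartition) of the original tree reappears. The
#' frequency at scale 1 is the ordinary bootstrap probability (BP); the full
#' scale curve feeds the approximately unbiased (AU) p-value fit of
#' [au_from_bp()].
#'
#' @param profiles list of `wdf_sample` objects or a `wdf_dataset`.
#' @param method `"nj"` (Neighbor-Joining, default) or `"average"` (UPGMA).
#' @param scales relative resample sizes; each scale r resamples
#'   `round(r * L)` of the L panel loci. Default `seq(0.5, 1.4, by = 0.1)`.
#' @param n_boot bootstrap replicates per scale (default 1000).
#' @param min_cotyped,metric passed to the distance computation.
#' @param seed integer seed; results are deterministic given it.
#' @return Object of class `wdf_support`: list with `clusters` (named list of
#'   leaf sets), `bp` (BP at scale 1 per cluster), `bp_by_scale` (clusters x
#'   scales matrix of frequencies), `counts` (integer appearance counts),
#'   `scales`, `n_boot`, `tree` (the original tree) and `method`.
#' @export
multiscale_bootstrap <- function(profiles, method = c("nj", "average"),
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 n_boot = 1000L, min_cotyped = 4L,
                                 metric = "dice", seed = 1L) {
  method <- match.arg(method)
  if (inherits(profiles, "wdf_dataset")) profiles <- dataset_samples(profiles)
  n <- length(profiles)
  if (n < 3L) stop("cluster support needs at least 3 profiles")
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("n_boot must be >= 1")
  loci <- sort(unique(unlist(lapply(profiles, function(p) names(p$calls)))))
  L <- length(loci)
  if (L < 2L) stop("multiscale bootstrap needs at least 2 loci")
  m_per_scale <- as.integer(round(scales * L))
  if (any(m_per_scale < 1L))
    stop("scale(s) ", paste(scales[m_per_scale < 1L], collapse = ", "),
         " resample zero loci")
  labels <- vapply(profiles, `[[`, character(1), "id")

  # per-locus similarity slices; NA marks a pair not co-typed at that locus
  S <- array(NA_real_, c(n, n, L), dimnames = list(labels, labels, loci))
  for (k in seq_len(L)) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      a <- profiles[[i]]$calls[[loci[[k]]]]
      b <- profiles[[j]]$calls[[loci[[k]]]]
      if (!is.null(a) && !is.null(b))
        S[i, j, k] <- S[j, i, k] <- locus_similarity(a, b, metric)
    }
    diag(S[, , k]) <- 1
  }
  build <- function(idx) {
    Ssub <- S[, , idx, drop = FALSE]
    cnt <- rowSums(!is.na(Ssub), dims = 2L)
    sim <- rowMeans(Ssub, na.rm = TRUE, dims = 2L)
    d <- 1 - sim
    d[cnt < min_cotyped] <- 1
    d[is.na(d)] <- 1
    diag(d) <- 0
    dimnames(d) <- list(labels, labels)
    if (method == "nj") neighbor_joining(d) else average_linkage(d)
  }
  tree0 <- build(seq_len(L))
  clusters <- tree_bipartitions(tree0)
  if (!length(clusters))
    stop("the original tree has no non-trivial internal edge")
  counts <- matrix(0L, length(clusters), length(scales),
                   dimnames = list(names(clusters), paste0("r", scales)))
  with_seed(seed, {
    for (si in seq_along(scales)) {
      m <- m_per_scale[[si]]
      for (b in seq_len(n_boot)) {
        idx <- sample.int(L, m, replace = TRUE)
        reps <- tryCatch(tree_bipartitions(build(idx)), error = function(e) list())
        hit <- names(clusters) %in% names(reps)
        counts[hit, si] <- counts[hit, si] + 1L
      }
    }
  })
  bp_by_scale <- counts / n_boot
  s1 <- which.min(abs(scales - 1))
  structure(list(clusters = clusters, bp = bp_by_scale[, s1],
                 bp_by_scale = bp_by_scale, counts = counts,
                 scales = scales, n_boot = n_boot, tree = tree0,
                 method = method),
            class = "wdf_support")
}

#' Approximately unbiased p-values from multiscale BP curves
#'
#' For each cluster, transforms the per-scale bootstrap frequencies to normal
#' quantiles, \eqn{z_r = \Phi^{-1}(1 - bp_r)}, and fits the multiscale model
#' \eqn{z_r = v \sqrt{r} + c / \sqrt{r}} by weighted least squares with the
#' binomial delta-method weights \eqn{n_{boot}\,\phi(z_r)^2 / (bp_r (1 -
#' bp_r))}. The signed distance v and curvature c give the approximately
#' unbiased p-value \eqn{au = 1 - \Phi(v - c)}. Scales with bp exactly 0 or 1
#' carry no usable quantile and are dropped; a cluster at bp = 0 (or 1) on
#' every scale falls back to au = 0 (au = 1).
#'
#' @param support a `wdf_support` from [multiscale_bootstrap()].
#' @return The support object with a `table` element added: a data frame with
#'   columns `cluster`, `bp`, `au`, `v`, `c`, `n_scales_used`.
#' @export
au_from_bp <- function(support) {
  stopifnot(inherits(support, "wdf_support"))
  r <- support$scales
  rows <- lapply(rownames(support$bp_by_scale), function(cl) {
    bp <- support$bp_by_scale[cl, ]
    fit <- au_fit_one(bp, r, support$n_boot)
    data.frame(cluster = cl, bp = unname(support$bp[cl]), au = fit$au,
               v = fit$v, c = fit$c, n_scales_used = fit$n_used,
               stringsAsFactors = FALSE)
  })
  support$table <- do.call(rbind, rows)
  rownames(support$table) <- NULL
  support
}

# WLS fit of one cluster's bp curve; exported via au_from_bp
#' @noRd
au_fit_one <- function(bp, r, n_boot) {
  usable <- bp > 0 & bp < 1
  if (!any(usable)) {
    if (all(bp == 0)) return(list(au = 0, v = Inf, c = 0, n_used = 0L))
    if (all(bp == 1)) return(list(au = 1, v = -Inf, c = 0, n_used = 0L))
  }
  if (sum(usable) < 2L || length(unique(r[usable])) < 2L)
    stop("degenerate AU fit: fewer than 2 scales with bp strictly in (0, 1)")
  rr <- r[usable]; bb <- bp[usable]
  z <- stats::qnorm(1 - bb)
  w <- n_boot * stats::dnorm(z)^2 / (bb * (1 - bb))
  X <- cbind(sqrt(rr), 1 / sqrt(rr))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[[1L]]; cc <- fit$coefficients[[2L]]
  list(au = 1 - stats::pnorm(v - cc), v = v, c = cc, n_used = sum(usable))
}

#' @export
print.wdf_support <- function(x, ...) {
  cat("Cluster support (", x$method, ", ", length(x$scales), " scales x ",
      x$n_boot, " replicates)\n", sep = "")
  if (!is.null(x$table)) {
    tab <- x$table
    tab$cluster <- substr(tab$cluster, 1, 40)
    print(tab, digits = 3)
  } else {
    print(data.frame(cluster = substr(names(x$bp), 1, 40), bp = unname(x$bp)),
          digits = 3)
  }
  invisible(x)
}
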