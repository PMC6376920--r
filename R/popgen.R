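#' Allele-frequency estimation from reference genotypes
#'
#' Gene-counting estimate over the diploid grapevine references: each typed
#' genotype contributes two gene copies (a homozygote contributes its allele
#' twice). Wines are mixtures, not diploid draws, so they are excluded by
#' default; `include_wines = TRUE` adds each wine allele once as a
#' pseudo-count for sensitivity analysis.
#'
#' @param samples list of `variety_genotype` (and optionally `wine_profile`)
#'   objects, or a `wdf_dataset`.
#' @param locus locus name.
#' @param include_wines include wine allele sets as single pseudo-counts.
#' @return Object of class `locus_frequencies`: list with `locus` and `freqs`
#'   (named numeric, names = allele sizes, summing to 1).
#' @export
estimate_frequencies <- function(samples, locus, include_wines = FALSE) {
  if (inherits(samples, "wdf_dataset"))
    samples <- c(samples$varieties, if (include_wines) samples$wines)
  copies <- integer(0)
  for (s in samples) {
    a <- s$calls[[locus]]
    if (is.null(a)) next
    if (inherits(s, "wine_profile")) {
      if (include_wines) copies <- c(copies, unique(a))
    } else copies <- c(copies, a)  # diploid: both copies count
  }
  if (!length(copies))
    stop("no sample typed at locus ", locus)
  tab <- table(copies)
  freqs <- as.numeric(tab) / sum(tab)
  structure(list(locus = locus,
                 freqs = stats::setNames(freqs, names(tab))),
            class = "locus_frequencies")
}

#' Probability of identity of one locus
#'
#' Probability that two random individuals share the same unordered genotype
#' at the locus under Hardy-Weinberg equilibrium:
#' \deqn{PI = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}
#' which equals \eqn{\sum_g P(g)^2} over all unordered genotypes.
#' `unbiased = TRUE` gives the small-sample corrected estimator
#' \deqn{\widehat{PI} = \frac{n^3(2a_2^2-a_4) - 2n^2(a_3+2a_2) + n(9a_2+2) - 6}
#'                           {(n-1)(n-2)(n-3)}}
#' with \eqn{a_k = \sum_i p_i^k} and `n` gene copies; the plain estimator is
#' the default and the one used for panel summaries.
#'
#' @param freqs a `locus_frequencies`.
#' @param unbiased apply the small-sample correction (requires `n`).
#' @param n number of gene copies behind the frequency estimate (for
#'   `unbiased = TRUE`).
#' @return PI in (0, 1].
#' @export
locus_pi <- function(freqs, unbiased = FALSE, n = NULL) {
  stopifnot(inherits(freqs, "locus_frequencies"))
  p <- unname(freqs$freqs)
  if (!unbiased) {
    pp <- outer(p, p)
    return(sum(p^4) + sum((2 * pp[upper.tri(pp)])^2))
  }
  if (is.null(n) || n < 4) stop("unbiased PI needs n >= 4 gene copies")
  a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
  (n^3 * (2 * a2^2 - a4) - 2 * n^2 * (a3 + 2 * a2) + n * (9 * a2 + 2) - 6) /
    ((n - 1) * (n - 2) * (n - 3))
}

#' Cumulative probability of identity of a panel
#'
#' Under independence across loci the panel PI is the product of the per-locus
#' values; it shrinks as loci are added, quantifying the discrimination power
#' gained by a larger marker set.
#'
#' @param pis numeric vector of per-locus PI values in (0, 1].
#' @return The product.
#' @export
cumulative_pi <- function(pis) {
  if (!length(pis)) stop("cumulative_pi needs at least one locus PI")
  if (any(pis <= 0 | pis > 1)) stop("per-locus PI values must be in (0, 1]")
  prod(pis)
}

#' Per-locus and cumulative PI of a dataset
#'
#' @param dataset a `wdf_dataset`.
#' @param include_wines passed to [estimate_frequencies()].
#' @param unbiased use the small-sample corrected per-locus estimator.
#' @return List with `table` (data frame: locus, n_alleles, n_copies, pi) and
#'   `cumulative_pi`. Loci with no typed reference are skipped.
#' @export
panel_pi <- function(dataset, include_wines = FALSE, unbiased = FALSE) {
  stopifnot(inherits(dataset, "wdf_dataset"))
  rows <- list()
  for (locus in dataset$panel$name) {
    fr <- tryCatch(estimate_frequencies(dataset, locus, include_wines),
                   error = function(e) NULL)
    if (is.null(fr)) next
    rows[[locus]] <- data.frame(
      locus = locus, n_alleles = length(fr$freqs),
      pi = locus_pi(fr, unbiased = unbiased,
                    n = if (unbiased) sum_gene_copies(dataset, locus, include_wines)))
  }
  if (!length(rows)) stop("no locus could be typed from the dataset")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, cumulative_pi = cumulative_pi(tab$pi))
}

#' @noRd
sum_gene_copies <- function(dataset, locus, include_wines) {
  n <- 0L
  for (s in dataset$varieties) if (!is.null(s$calls[[locus]])) n <- n + 2L
  if (include_wines)
    for (s in dataset$wines)
      if (!is.null(s$calls[[locus]])) n <- n + length(unique(s$calls[[locus]]))
  n
}

#' Random match probability of a profile
#'
#' Probability of observing one specific diploid profile under Hardy-Weinberg
#' allele frequencies: the product over typed loci of \eqn{p_i^2}
#' (homozygote) or \eqn{2 p_i p_j} (heterozygote). Loci untyped in the
#' genotype, or absent from the frequency list, are skipped. An allele missing
#' from its spectrum is substituted with the smallest observed frequency at
#' that locus and the result gains a `substituted` attribute naming the loci.
#'
#' @param genotype a `variety_genotype`.
#' @param freqs list of `locus_frequencies`.
#' @return RMP in (0, 1], with attributes `n_loci` and (possibly)
#'   `substituted`.
#' @export
random_match_probability <- function(genotype, freqs) {
  stopifnot(inherits(genotype, "variety_genotype"))
  names(freqs) <- vapply(freqs, `[[`, character(1), "locus")
  rmp <- 1; used <- 0L; subs <- character(0)
  for (locus in names(genotype$calls)) {
    fr <- freqs[[locus]]
    if (is.null(fr)) next
    a <- genotype$calls[[locus]]
    p <- fr$freqs[as.character(a)]
    if (anyNA(p)) {
      p[is.na(p)] <- min(fr$freqs)
      subs <- c(subs, locus)
    }
    rmp <- rmp * if (a[[1L]] == a[[2L]]) p[[1L]]^2 else 2 * p[[1L]] * p[[2L]]
    used <- used + 1L
  }
  if (used == 0L) stop("genotype shares no typed locus with the frequency list")
  attr(rmp, "n_loci") <- used
  if (length(subs)) attr(rmp, "substituted") <- subs
  rmp
}
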