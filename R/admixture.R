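#' Inclusion score of a candidate variety in a wine
#'
#' Fraction of the candidate's allele copies found in the wine's validated
#' allele sets, over loci typed in both. A homozygote contributes its single
#' distinct allele with weight two; a heterozygote contributes each allele
#' once. The score is 1 exactly when every candidate allele copy appears at
#' every co-typed locus, 0 when none does, and is deliberately insensitive to
#' *extra* wine alleles (those come from other blend components and affect
#' the distance, not inclusion). It is a deterministic compatibility score,
#' not a calibrated probability.
#'
#' @param wine a `wine_profile`.
#' @param candidate a `variety_genotype`.
#' @param min_cotyped minimum co-typed loci for a conclusive call (default 4).
#' @return List with `score` in \[0, 1\] (NA if no co-typed locus) and
#'   `n_cotyped`.
#' @export
inclusion_score <- function(wine, candidate, min_cotyped = 4L) {
  stopifnot(inherits(wine, "wine_profile"), inherits(candidate, "variety_genotype"))
  shared <- intersect(names(wine$calls), names(candidate$calls))
  if (!length(shared)) return(list(score = NA_real_, n_cotyped = 0L))
  matched <- 0L
  for (locus in shared) {
    cand <- candidate$calls[[locus]]
    wset <- wine$calls[[locus]]
    if (cand[[1L]] == cand[[2L]]) {
      matched <- matched + 2L * (cand[[1L]] %in% wset)
    } else {
      matched <- matched + sum(cand %in% wset)
    }
  }
  list(score = matched / (2 * length(shared)), n_cotyped = length(shared))
}

#' Assess candidate varieties against a wine profile
#'
#' Scores each candidate by [inclusion_score()] and [profile_distance()] and
#' calls presence: `compatible` when the inclusion score reaches the
#' threshold `theta`, `excluded` below it, and `inconclusive` when fewer than
#' `min_cotyped` loci are typed in both (too little shared evidence to call
#' either way). The default `theta = 0.75` tolerates roughly one dropped
#' allele copy per two loci on a seven-locus comparison, the working margin
#' for degraded wine DNA.
#'
#' @param wine a `wine_profile`.
#' @param candidates list of `variety_genotype` (>= 1).
#' @param theta inclusion-score threshold in (0, 1] (default 0.75).
#' @param min_cotyped minimum co-typed loci (default 4).
#' @param metric distance metric, see [locus_similarity()].
#' @return Object of class `wdf_assessment`: a data frame with columns
#'   `wine_id`, `variety_id`, `inclusion_score`, `distance`, `n_cotyped`,
#'   `presence_call`, sorted by ascending distance (ties: descending score,
#'   then label).
#' @export
assess_candidates <- function(wine, candidates, theta = 0.75, min_cotyped = 4L,
                              metric = "dice") {
  if (!length(candidates)) stop("assess_candidates needs at least one candidate")
  rows <- lapply(candidates, function(cand) {
    inc <- inclusion_score(wine, cand, min_cotyped)
    pd <- profile_distance(wine, cand, min_cotyped, metric)
    call <- if (inc$n_cotyped < min_cotyped) "inconclusive"
            else if (inc$score >= theta) "compatible" else "excluded"
    data.frame(wine_id = wine$id, variety_id = cand$id,
               inclusion_score = inc$score, distance = pd$distance,
               n_cotyped = inc$n_cotyped, presence_call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$distance, -out$inclusion_score, out$variety_id), ]
  rownames(out) <- NULL
  attr(out, "theta") <- theta
  attr(out, "min_cotyped") <- as.integer(min_cotyped)
  class(out) <- c("wdf_assessment", "data.frame")
  out
}

#' Assign the main varietal component
#'
#' The main component is the comparable candidate at smallest allele-sharing
#' distance. The margin to the runner-up guards against over-reading: when it
#' falls below `epsilon` the assignment is reported ambiguous — varieties can
#' be near-indistinguishable on a given marker panel (the classic
#' Cabernet-Sauvignon/Merlot confusability), and a hair's-breadth ranking
#' should not be sold as a call.
#'
#' @param assessments a `wdf_assessment`.
#' @param epsilon minimum distance margin for an unambiguous call
#'   (default 0.02).
#' @return Object of class `wdf_assignment`: list with `wine_id`, `variety`
#'   (`NA` when no comparable candidate), `margin` (`NA` with a single
#'   comparable candidate), `ambiguous`, `no_call`, and `runner_up`.
#' @export
assign_main_variety <- function(assessments, epsilon = 0.02) {
  stopifnot(inherits(assessments, "wdf_assessment"))
  ok <- assessments[assessments$presence_call != "inconclusive", , drop = FALSE]
  if (!nrow(ok))
    return(structure(list(wine_id = assessments$wine_id[[1L]], variety = NA_character_,
                          margin = NA_real_, ambiguous = FALSE, no_call = TRUE,
                          runner_up = NA_character_),
                     class = "wdf_assignment"))
  best <- ok[1L, ]   # assessments arrive sorted by distance
  if (nrow(ok) == 1L)
    return(structure(list(wine_id = best$wine_id, variety = best$variety_id,
                          margin = NA_real_, ambiguous = FALSE, no_call = FALSE,
                          runner_up = NA_character_),
                     class = "wdf_assignment"))
  margin <- ok$distance[[2L]] - ok$distance[[1L]]
  structure(list(wine_id = best$wine_id, variety = best$variety_id,
                 margin = margin, ambiguous = margin < epsilon,
                 no_call = FALSE, runner_up = ok$variety_id[[2L]]),
            class = "wdf_assignment")
}

#' @export
print.wdf_assignment <- function(x, ...) {
  if (x$no_call) {
    cat("Wine '", x$wine_id, "': no call (no comparable candidate)\n", sep = "")
  } else if (x$ambiguous) {
    cat("Wine '", x$wine_id, "': ambiguous between '", x$variety,
        "' and '", x$runner_up, "' (margin ", format(x$margin, digits = 3),
        ")\n", sep = "")
  } else {
    cat("Wine '", x$wine_id, "': main varietal component '", x$variety, "'",
        if (!is.na(x$margin)) paste0(" (margin ", format(x$margin, digits = 3), ")"),
        "\n", sep = "")
  }
  invisible(x)
}

#' PCA ordination of allele incidence
#'
#' Encodes every profile as a binary incidence vector over all observed
#' (locus, allele) pairs, column-centers the matrix, and projects onto the
#' leading right singular directions. Presence/absence encoding is used
#' because wine profiles are allele *sets* — copy numbers are unobservable in
#' a mixture.
#'
#' @param profiles list of `wdf_sample` objects or a `wdf_dataset` (>= 2).
#' @param n_components components to keep (default 2; capped at
#'   `min(samples - 1, features)`).
#' @return Object of class `wdf_ordination`: list with `labels`,
#'   `coordinates` (samples x components), `explained_variance_ratio`,
#'   and `features`.
#' @export
ordinate <- function(profiles, n_components = 2L) {
  if (inherits(profiles, "wdf_dataset")) profiles <- dataset_samples(profiles)
  n <- length(profiles)
  if (n < 2L) stop("ordination needs at least 2 profiles")
  labels <- vapply(profiles, `[[`, character(1), "id")
  feats <- sort(unique(unlist(lapply(profiles, function(p)
    unlist(lapply(names(p$calls), function(l)
      paste0(l, ":", unique(p$calls[[l]]))))))))
  X <- matrix(0, n, length(feats), dimnames = list(labels, feats))
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    f <- unlist(lapply(names(p$calls), function(l)
      paste0(l, ":", unique(p$calls[[l]]))))
    X[i, f] <- 1
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  k <- min(n_components, n - 1L, ncol(X))
  sv <- svd(Xc)
  total_var <- sum(Xc^2)
  evr <- if (total_var > 0) sv$d^2 / total_var else rep(0, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(coords) <- list(labels, paste0("PC", seq_len(k)))
  structure(list(labels = labels, coordinates = coords,
                 explained_variance_ratio = evr[seq_len(k)],
                 features = feats),
            class = "wdf_ordination")
}

#' @export
print.wdf_ordination <- function(x, ...) {
  cat("PCA of allele incidence: ", length(x$labels), " samples, ",
      length(x$features), " locus:allele features\n", sep = "")
  cat("explained variance ratio:",
      paste(format(x$explained_variance_ratio, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.wdf_ordination <- function(x, components = c(1, 2), ...) {
  co <- x$coordinates
  if (ncol(co) < 2) stop("need at least 2 components to plot")
  plot(co[, components[1]], co[, components[2]],
       xlab = colnames(co)[components[1]], ylab = colnames(co)[components[2]],
       main = "Allele-incidence PCA", ...)
  graphics::text(co[, components[1]], co[, components[2]], labels = x$labels,
                 pos = 3, cex = 0.7)
  invisible(x)
}

#' Bundle one wine's analysis into a report
#'
#' @param wine a `wine_profile`.
#' @param assessments a `wdf_assessment` for this wine.
#' @param assignment a `wdf_assignment` for this wine.
#' @param tree optional `ape::phylo` (serialized as Newick).
#' @param support optional `wdf_support` (after [au_from_bp()]).
#' @param ordination optional `wdf_ordination`.
#' @param panel_pi optional result of [panel_pi()].
#' @return Object of class `wdf_report`; `as_json()` yields the JSON
#'   document, `print()` a human-readable summary.
#' @export
admixture_report <- function(wine, assessments, assignment, tree = NULL,
                             support = NULL, ordination = NULL,
                             panel_pi = NULL) {
  ids <- unique(c(wine$id, assessments$wine_id, assignment$wine_id))
  if (length(ids) != 1L)
    stop("wine ids disagree across report inputs: ", paste(ids, collapse = ", "))
  structure(list(
    wine_id = wine$id,
    profile = wine$calls,
    assessments = as.data.frame(assessments),
    assignment = unclass(assignment),
    newick = if (!is.null(tree)) to_newick(tree),
    support = if (!is.null(support)) support$table,
    ordination = if (!is.null(ordination))
      list(coordinates = ordination$coordinates,
           explained_variance_ratio = ordination$explained_variance_ratio),
    cumulative_pi = if (!is.null(panel_pi)) panel_pi$cumulative_pi
  ), class = "wdf_report")
}

#' @rdname admixture_report
#' @param report a `wdf_report`.
#' @export
as_json <- function(report) {
  stopifnot(inherits(report, "wdf_report"))
  jsonlite::toJSON(report[!vapply(report, is.null, logical(1))],
                   auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' @export
print.wdf_report <- function(x, ...) {
  cat("=== WDF admixture report: wine '", x$wine_id, "' ===\n", sep = "")
  print(x$assessments, digits = 3)
  print(structure(x$assignment, class = "wdf_assignment"))
  if (!is.null(x$cumulative_pi))
    cat("panel cumulative PI:", format(x$cumulative_pi, digits = 3), "\n")
  if (!is.null(x$newick)) cat("tree:", x$newick, "\n")
  invisible(x)
}
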