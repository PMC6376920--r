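#' Synthetic genotyping data for the wine fingerprinting pipeline
#'
#' Wet-lab SSR typing of wine is expensive and slow, so the pipeline ships a
#' generator that emulates its statistical structure end to end: per-locus
#' allele-frequency spectra on the repeat grid, Hardy-Weinberg diploid
#' reference genotypes, wines as proportion-weighted blends of varieties, and
#' replicated peak observations subject to allele dropout (worsening with wine
#' age and with smaller blend proportion), rare allele drop-in, and sub-bp
#' sizing jitter.
#'
#' @name synthetic-data
NULL

# run expr with a private RNG stream; caller's RNG state untouched
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Simulate per-locus allele-frequency spectra
#'
#' For each panel locus, places `n_alleles` allele sizes on the repeat-unit
#' grid above a locus-specific base size and draws their population
#' frequencies from a symmetric Dirichlet distribution. The spectra play the
#' role of a reference-collection frequency database: they parameterize
#' Hardy-Weinberg genotype simulation, drop-in allele draws, and the
#' probability-of-identity statistics.
#'
#' @param panel a `wdf_panel`.
#' @param n_alleles alleles per locus (>= 1).
#' @param concentration Dirichlet concentration (> 0). Values near 1 give the
#'   uneven frequency spectra typical of grapevine SSR panels; large values
#'   approach equifrequent alleles.
#' @param seed integer seed; output is a deterministic function of it.
#' @return Named list (by locus) of `allele_spectrum` objects, each with
#'   elements `locus`, `alleles` (increasing integer sizes) and `freqs`
#'   (probabilities summing to one).
#' @export
simulate_frequency_panel <- function(panel, n_alleles = 8L, concentration = 1,
                                     seed = 1L) {
  stopifnot(inherits(panel, "wdf_panel"))
  n_alleles <- as.integer(n_alleles)
  if (n_alleles < 1L) stop("n_alleles must be >= 1")
  if (concentration <= 0) stop("concentration must be positive")
  with_seed(seed, {
    out <- lapply(seq_len(nrow(panel)), function(i) {
      lr <- panel[i, ]
      span <- lr$size_max - lr$size_min
      need <- (n_alleles - 1L) * lr$repeat_unit
      if (need > span - 2L)
        stop("locus ", lr$name, ": ", n_alleles,
             " alleles do not fit between the plausibility bounds")
      base <- lr$size_min + 1L +
        lr$repeat_unit * sample.int(max(1L, (span - 2L - need) %/% lr$repeat_unit + 1L), 1L) - lr$repeat_unit
      alleles <- base + lr$repeat_unit * (seq_len(n_alleles) - 1L)
      g <- stats::rgamma(n_alleles, shape = concentration)
      while (sum(g) == 0) g <- stats::rgamma(n_alleles, shape = concentration)
      allele_spectrum(lr$name, alleles, g / sum(g))
    })
    stats::setNames(out, panel$name)
  })
}

#' @rdname simulate_frequency_panel
#' @param locus locus name.
#' @param alleles strictly increasing integer allele sizes.
#' @param freqs probabilities, same length as `alleles`, summing to 1.
#' @export
allele_spectrum <- function(locus, alleles, freqs) {
  alleles <- as.integer(alleles)
  freqs <- as.numeric(freqs)
  if (length(alleles) != length(freqs)) stop("alleles and freqs lengths differ")
  if (is.unsorted(alleles, strictly = TRUE)) stop("alleles must be strictly increasing")
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-12) stop("frequencies must sum to 1")
  structure(list(locus = locus, alleles = alleles, freqs = freqs),
            class = "allele_spectrum")
}

#' Simulate a diploid reference genotype under Hardy-Weinberg equilibrium
#'
#' Draws two independent alleles per locus from each spectrum.
#'
#' @param spectra named list of `allele_spectrum` (one per locus).
#' @param variety_id name for the simulated variety.
#' @param seed integer seed.
#' @return A `variety_genotype`.
#' @export
simulate_variety <- function(spectra, variety_id, seed = 1L) {
  if (!length(spectra)) stop("need at least one allele spectrum")
  with_seed(seed, {
    calls <- lapply(spectra, function(sp) {
      idx <- sample.int(length(sp$alleles), 2L, replace = TRUE, prob = sp$freqs)
      sort(sp$alleles[idx])
    })
    names(calls) <- vapply(spectra, `[[`, character(1), "locus")
    variety_genotype(variety_id, calls)
  })
}

#' Allele dropout / drop-in model
#'
#' Low-template, degraded grapevine DNA in wine loses true alleles
#' stochastically (dropout) and occasionally gains spurious ones (drop-in).
#' The per-allele detection probability is modelled as
#' `p_base * proportion^gamma * exp(-lam * age_years)`: detection is best for
#' a fresh monovarietal wine and decays both with wine age and with the blend
#' proportion of the contributing variety.
#'
#' @param p_base baseline per-allele detection probability in (0, 1]
#'   (default 0.98).
#' @param gamma exponent on the blend proportion (>= 0, default 0.15).
#' @param lam age decay rate per year (>= 0, default 0.05).
#' @param p_dropin per-locus per-replica drop-in probability in \[0, 0.5)
#'   (default 0.01).
#' @return Object of class `dropout_model`.
#' @export
dropout_model <- function(p_base = 0.98, gamma = 0.15, lam = 0.05,
                          p_dropin = 0.01) {
  if (!(p_base > 0 && p_base <= 1)) stop("p_base must be in (0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  if (lam < 0) stop("lam must be >= 0")
  if (p_dropin < 0 || p_dropin >= 0.5) stop("p_dropin must be in [0, 0.5)")
  structure(list(p_base = p_base, gamma = gamma, lam = lam, p_dropin = p_dropin),
            class = "dropout_model")
}

#' @rdname dropout_model
#' @param model a `dropout_model`.
#' @param proportion blend proportion of the contributing variety, in (0, 1].
#' @param age_years wine age in years (>= 0).
#' @return `detection_probability()` returns the per-allele detection
#'   probability, clamped to \[0, 1\].
#' @export
detection_probability <- function(model, proportion, age_years) {
  stopifnot(inherits(model, "dropout_model"))
  if (any(proportion <= 0) || any(proportion > 1))
    stop("proportion must be in (0, 1]")
  if (any(age_years < 0)) stop("age_years must be >= 0")
  p <- model$p_base * proportion^model$gamma * exp(-model$lam * age_years)
  pmin(pmax(p, 0), 1)
}

#' Blend specification for a simulated wine
#'
#' @param wine_id wine name.
#' @param components named numeric vector of blend proportions by variety id,
#'   each in (0, 1], summing to 1.
#' @param age_years wine age in years (>= 0).
#' @param n_replicas technical replicas to simulate (>= 3, the working
#'   minimum for wines; 3 to 6 depending on wine complexity).
#' @return Object of class `blend_spec`.
#' @export
blend_spec <- function(wine_id, components, age_years = 0, n_replicas = 3L) {
  check_sample_id(wine_id)
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("components must be named by variety id")
  if (any(components <= 0) || any(components > 1))
    stop("proportions must be in (0, 1]")
  if (abs(sum(components) - 1) > 1e-9) stop("proportions must sum to 1")
  if (age_years < 0) stop("age_years must be >= 0")
  n_replicas <- as.integer(n_replicas)
  if (n_replicas < 3L) stop("wines require at least 3 technical replicas")
  structure(list(wine_id = wine_id, components = components,
                 age_years = age_years, n_replicas = n_replicas),
            class = "blend_spec")
}

#' Simulate replicated peak observations for a blended wine
#'
#' For each technical replica and locus, every distinct allele of every blend
#' component is detected independently with probability
#' [detection_probability()] evaluated at that component's proportion and the
#' wine's age. With probability `p_dropin` one spurious allele, drawn from the
#' locus spectrum excluding the true contributing alleles, is added. Observed
#' sizes are jittered uniformly by up to 0.4 bp around the integer allele —
#' small enough that binning at a 2 bp repeat unit stays unambiguous — and
#' peak heights are drawn lognormally around the contributing proportion
#' (heights are cosmetic; nothing downstream consumes them).
#'
#' @param blend a `blend_spec`.
#' @param varieties list of `variety_genotype` covering every blend component.
#' @param model a `dropout_model`.
#' @param spectra named list of `allele_spectrum` (drop-in source).
#' @param seed integer seed.
#' @return List of `replica_observation`, one per technical replica.
#' @export
simulate_wine_replicas <- function(blend, varieties, model, spectra, seed = 1L) {
  stopifnot(inherits(blend, "blend_spec"), inherits(model, "dropout_model"))
  names(varieties) <- vapply(varieties, `[[`, character(1), "id")
  missing <- setdiff(names(blend$components), names(varieties))
  if (length(missing))
    stop("no genotype supplied for blend component(s): ",
         paste(missing, collapse = ", "))
  loci <- vapply(spectra, `[[`, character(1), "locus")
  with_seed(seed, {
    lapply(seq_len(blend$n_replicas), function(r) {
      peaks <- list()
      for (li in seq_along(spectra)) {
        locus <- loci[[li]]
        true_alleles <- integer(0)
        det_height <- numeric(0)   # named by allele; one peak per detected size
        for (v in names(blend$components)) {
          call <- varieties[[v]]$calls[[locus]]
          if (is.null(call)) next
          true_alleles <- union(true_alleles, call)
          prop <- blend$components[[v]]
          p <- detection_probability(model, prop, blend$age_years)
          for (a in unique(call)) {
            if (stats::runif(1) < p) {
              key <- as.character(a)
              h <- prop * 1000 * stats::rlnorm(1, 0, 0.25)
              det_height[key] <- if (is.na(det_height[key])) h
                                 else det_height[[key]] + h
            }
          }
        }
        det <- as.integer(names(det_height))
        sizes <- if (length(det)) det + stats::runif(length(det), -0.4, 0.4)
                 else numeric(0)
        heights <- unname(det_height)
        if (stats::runif(1) < model$p_dropin) {
          pool <- setdiff(spectra[[li]]$alleles, true_alleles)
          if (length(pool)) {
            w <- spectra[[li]]$freqs[match(pool, spectra[[li]]$alleles)]
            a <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = w)
            sizes <- c(sizes, a + stats::runif(1, -0.4, 0.4))
            heights <- c(heights, 50 * stats::rlnorm(1, 0, 0.25))
          }
        }
        if (length(sizes))
          peaks[[locus]] <- data.frame(size = sizes, height = heights)
      }
      replica_observation(blend$wine_id, r, peaks)
    })
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper tying the generator together: draws frequency spectra,
#' a set of reference varieties, and replicated wine observations for each
#' blend, returning everything downstream stages need plus the ground truth.
#'
#' @param panel a `wdf_panel` (default [default_panel()]).
#' @param n_varieties number of reference varieties to simulate.
#' @param blends list of `blend_spec`; component names must be among the
#'   simulated variety ids `V1..Vk` (or supply `varieties` yourself).
#' @param model a `dropout_model`.
#' @param n_alleles,concentration passed to [simulate_frequency_panel()].
#' @param seed integer master seed; all randomness derives from it.
#' @return List with `panel`, `spectra`, `varieties` (named list),
#'   `replicas` (named list of replica lists, by wine id), and `truth`
#'   (the blend specs).
#' @export
simulate_study <- function(panel = default_panel(), n_varieties = 4L,
                           blends = list(), model = dropout_model(),
                           n_alleles = 8L, concentration = 1, seed = 1L) {
  seed <- as.integer(seed)
  spectra <- simulate_frequency_panel(panel, n_alleles, concentration, seed = seed)
  varieties <- lapply(seq_len(n_varieties), function(i)
    simulate_variety(spectra, paste0("V", i), seed = seed + 104729L * i))
  names(varieties) <- vapply(varieties, `[[`, character(1), "id")
  replicas <- lapply(seq_along(blends), function(i)
    simulate_wine_replicas(blends[[i]], varieties, model, spectra,
                           seed = seed + 224737L * i))
  names(replicas) <- vapply(blends, `[[`, character(1), "wine_id")
  list(panel = panel, spectra = spectra, varieties = varieties,
       replicas = replicas, truth = blends)
}
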