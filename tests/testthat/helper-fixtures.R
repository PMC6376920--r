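# Shared fixtures: small panels, profiles and oracle helpers built in code.

# compact 7-locus panel with wide, uniform bounds (easier arithmetic than the
# marker-specific defaults)
toy_panel <- function(n = 7L) {
  wdf_panel(paste0("L", seq_len(n)), repeat_unit = 2L,
            size_min = 80L, size_max = 400L)
}

toy_variety <- function(id, sizes, panel = toy_panel(length(sizes))) {
  calls <- lapply(sizes, function(s) as.integer(s))
  names(calls) <- panel$name[seq_along(sizes)]
  variety_genotype(id, calls, panel)
}

# brute-force probability of identity: sum over all unordered HWE genotypes
# of P(g)^2 (the independent oracle for locus_pi)
pi_oracle <- function(p) {
  s <- 0
  n <- length(p)
  for (i in seq_len(n)) for (j in i:n) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    s <- s + pg^2
  }
  s
}

# random tree with strictly positive branch lengths and its additive
# distance matrix (oracle for Neighbor-Joining exactness)
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
  tr$tip.label <- sort(tr$tip.label)[sample.int(n)]
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# canonical bipartition keys of a phylo, for topology comparison
bip_keys <- function(tree) sort(names(tree_bipartitions(tree)))

# exhaustive walk-count oracle: enumerate all node sequences of length k
walks_brute <- function(A, k, p, q) {
  n <- nrow(A)
  seqs <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), k - 1L)))
  if (k == 1L) return(A[p, q])
  total <- 0
  for (r in seq_len(nrow(seqs))) {
    path <- c(p, seqs[r, ], q)
    w <- 1
    for (s in seq_len(k)) w <- w * A[path[s], path[s + 1L]]
    total <- total + w
  }
  total
}

# default-condition synthetic study: 4 varieties, one blended wine
sim_blend_run <- function(components, age, seed, n_alleles = 8L,
                          panel = default_panel()) {
  study <- simulate_study(
    panel = panel, n_varieties = 4L,
    blends = list(blend_spec("W", components, age_years = age, n_replicas = 3L)),
    model = dropout_model(), n_alleles = n_alleles, seed = seed)
  prof <- consensus_profile(study$replicas$W, panel)
  list(study = study, profile = prof)
}
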