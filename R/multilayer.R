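#' Multiplex-network integration of wine evidence layers
#'
#' Different kinds of evidence about the same set of wines — DNA-profile
#' similarity, chemical similarity, provenance metadata — form the layers of
#' a multiplex network: within a layer, wines are connected by weighted
#' similarity edges; across layers, each wine is connected to its own copy
#' with an interlayer strength. The supra-adjacency matrix stacks the layer
#' adjacencies on the block diagonal with `omega[i, j] * I` off-diagonal.
#' Powers of this matrix count weighted walks; its exponential gives the
#' communicability between any two node copies; and averaging communicability
#' over layer copies aggregates the layers into a single similarity network
#' whose interlayer strengths can be fitted against a response network.
#'
#' @name multilayer
NULL

#' @rdname multilayer
#' @param layer_name layer label.
#' @param nodes ordered character vector of wine labels.
#' @param adjacency symmetric numeric matrix, weights in \[0, 1\], zero
#'   diagonal.
#' @return `layer_graph()` returns an object of class `layer_graph`.
#' @export
layer_graph <- function(layer_name, nodes, adjacency) {
  nodes <- as.character(nodes)
  A <- as.matrix(adjacency)
  if (nrow(A) != length(nodes) || ncol(A) != length(nodes))
    stop("adjacency dimension must match the node count")
  if (max(abs(A - t(A))) > 1e-12) stop("layer adjacency must be symmetric")
  if (any(A < 0 | A > 1)) stop("layer weights must be in [0, 1]")
  if (any(diag(A) != 0)) stop("layer adjacency must have a zero diagonal")
  dimnames(A) <- list(nodes, nodes)
  structure(list(layer_name = layer_name, nodes = nodes, adjacency = A),
            class = "layer_graph")
}

#' @rdname multilayer
#' @param h number of layers.
#' @param omega either a scalar (shared strength for every layer pair) or a
#'   symmetric h x h matrix with zero diagonal and entries in \[0, 1\], where
#'   zero means independent layers and one total dependence.
#' @return `interlayer_weights()` returns a validated h x h matrix.
#' @export
interlayer_weights <- function(h, omega) {
  if (length(omega) == 1L) {
    W <- matrix(omega, h, h); diag(W) <- 0
  } else W <- as.matrix(omega)
  if (nrow(W) != h || ncol(W) != h)
    stop("omega must be ", h, " x ", h)
  if (max(abs(W - t(W))) > 1e-12) stop("interlayer strengths must be symmetric")
  if (any(diag(W) != 0)) stop("omega diagonal must be zero")
  if (any(W < 0 | W > 1)) stop("interlayer strengths must be in [0, 1]")
  W
}

#' Build the supra-adjacency matrix of a multiplex network
#'
#' @param layers list of `layer_graph` sharing node set and order.
#' @param omega scalar or h x h interlayer strength matrix (see
#'   [interlayer_weights()]).
#' @return Object of class `supra_adjacency`: list with `M` (the
#'   `(h n) x (h n)` matrix, rows/cols named `layer::node`), `layers`,
#'   `nodes`, `h`, `n`, `omega`.
#' @export
build_supra <- function(layers, omega = 0) {
  if (!length(layers)) stop("need at least one layer")
  stopifnot(all(vapply(layers, inherits, logical(1), "layer_graph")))
  nodes <- layers[[1L]]$nodes
  for (l in layers)
    if (!identical(l$nodes, nodes))
      stop("layer '", l$layer_name, "' does not share the node order")
  h <- length(layers); n <- length(nodes)
  W <- interlayer_weights(h, omega)
  M <- matrix(0, h * n, h * n)
  lnames <- vapply(layers, `[[`, character(1), "layer_name")
  rn <- as.vector(vapply(lnames, function(l) paste0(l, "::", nodes),
                         character(n)))
  dimnames(M) <- list(rn, rn)
  for (i in seq_len(h)) for (j in seq_len(h)) {
    ri <- (i - 1L) * n + seq_len(n); rj <- (j - 1L) * n + seq_len(n)
    M[ri, rj] <- if (i == j) layers[[i]]$adjacency else W[i, j] * diag(n)
  }
  structure(list(M = M, layers = lnames, nodes = nodes, h = h, n = n,
                 omega = W),
            class = "supra_adjacency")
}

# flat index of a (layer, node) copy; accepts names or indices
#' @noRd
supra_index <- function(s, layer, node) {
  li <- if (is.character(layer)) match(layer, s$layers) else as.integer(layer)
  ni <- if (is.character(node)) match(node, s$nodes) else as.integer(node)
  if (is.na(li) || li < 1L || li > s$h) stop("unknown layer: ", layer)
  if (is.na(ni) || ni < 1L || ni > s$n) stop("unknown node: ", node)
  (li - 1L) * s$n + ni
}

#' Weighted walk counts in the multiplex
#'
#' The (p, q) entry of the k-th power of the supra-adjacency matrix is the
#' weight-sum over all walks of length k between the two node copies.
#'
#' @param supra a `supra_adjacency`.
#' @param k walk length (integer >= 1).
#' @param p,q node copies, each given as `c(layer, node)` (names or indices).
#' @return The weighted walk count; with `p` or `q` missing, the full matrix
#'   power.
#' @export
count_walks <- function(supra, k, p = NULL, q = NULL) {
  stopifnot(inherits(supra, "supra_adjacency"))
  k <- as.integer(k)
  if (k < 1L) stop("walk length k must be >= 1")
  P <- supra$M
  for (i in seq_len(k - 1L)) P <- P %*% supra$M
  if (is.null(p) || is.null(q)) return(P)
  P[supra_index(supra, p[[1L]], p[[2L]]),
    supra_index(supra, q[[1L]], q[[2L]])]
}

#' Communicability between node copies
#'
#' The communicability between p and q weights every walk of length k by
#' 1/k!, summing to the (p, q) entry of the matrix exponential `expm(M)`
#' (the k = 0 identity term included).
#'
#' @param supra a `supra_adjacency`.
#' @param p,q node copies as in [count_walks()]; with either missing the full
#'   communicability matrix is returned.
#' @return Non-negative real, or the full matrix.
#' @export
communicability <- function(supra, p = NULL, q = NULL) {
  stopifnot(inherits(supra, "supra_adjacency"))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(supra$M)))
  dimnames(E) <- dimnames(supra$M)
  if (is.null(p) || is.null(q)) return(E)
  E[supra_index(supra, p[[1L]], p[[2L]]),
    supra_index(supra, q[[1L]], q[[2L]])]
}

#' Aggregate the layers into one similarity network
#'
#' For each wine pair (p, q), sums the communicability over all layer-copy
#' pairs and averages over the layers:
#' `agg(p, q) = sum_{i,j} expm(M)[p_i, q_j] / h`. With all interlayer
#' strengths zero the blocks decouple and this is the plain mean of the
#' per-layer communicabilities. The diagonal is set to zero.
#'
#' @param layers list of `layer_graph`.
#' @param omega scalar or h x h interlayer strengths.
#' @return Symmetric n x n matrix over the wines, zero diagonal.
#' @export
aggregate_layer <- function(layers, omega = 0) {
  s <- build_supra(layers, omega)
  E <- communicability(s)
  n <- s$n; h <- s$h
  agg <- matrix(0, n, n, dimnames = list(s$nodes, s$nodes))
  for (i in seq_len(h)) for (j in seq_len(h)) {
    ri <- (i - 1L) * n + seq_len(n); rj <- (j - 1L) * n + seq_len(n)
    agg <- agg + E[ri, rj]
  }
  # normalize by the layer count: with decoupled layers (omega = 0) the
  # cross-layer blocks vanish and this is the plain mean of the per-layer
  # communicabilities; with h = 1 it reduces to expm(A_1)
  agg <- agg / h
  diag(agg) <- 0
  (agg + t(agg)) / 2
}

#' Fit interlayer strengths against a response network
#'
#' Grid search for the interlayer strength minimizing the sum of squared
#' differences between the aggregate network's edge weights and a response
#' network's, over wine pairs p < q. By default a single shared scalar omega
#' is searched over `{0, step, ..., 1}`; `full_matrix = TRUE` searches every
#' upper-triangle entry independently (cost grows as
#' `(1/step + 1)^(h(h-1)/2)`, so it is restricted to h <= 4). Ties go to the
#' smallest omega (lexicographically for the matrix search).
#'
#' @param layers list of `layer_graph`.
#' @param response symmetric numeric matrix over the same wines.
#' @param step grid step in (0, 0.5].
#' @param full_matrix search all pairwise strengths instead of one scalar.
#' @return List with `omega` (scalar or matrix), `objective`, and `grid`
#'   (data frame of visited values and objectives, scalar search only).
#' @export
fit_omega <- function(layers, response, step = 0.1, full_matrix = FALSE) {
  if (step <= 0 || step > 0.5) stop("grid step must be in (0, 0.5]")
  response <- as.matrix(response)
  n <- length(layers[[1L]]$nodes)
  if (!all(dim(response) == n))
    stop("response dimension does not match the layer node count")
  if (max(abs(response - t(response))) > 1e-12)
    stop("response network must be symmetric")
  h <- length(layers)
  ut <- upper.tri(response)
  obj <- function(W) {
    agg <- aggregate_layer(layers, W)
    sum((agg[ut] - response[ut])^2)
  }
  grid_vals <- seq(0, 1, by = step)
  if (grid_vals[length(grid_vals)] < 1) grid_vals <- c(grid_vals, 1)
  if (h == 1L || !full_matrix) {
    objs <- vapply(grid_vals, function(w) obj(if (h == 1L) 0 else w), numeric(1))
    best <- which.min(objs)   # which.min takes the first, i.e. smallest omega
    return(list(omega = grid_vals[[best]], objective = objs[[best]],
                grid = data.frame(omega = grid_vals, objective = objs)))
  }
  if (h > 4L) stop("full-matrix search is restricted to h <= 4 layers")
  npair <- h * (h - 1L) / 2L
  combos <- do.call(expand.grid, rep(list(grid_vals), npair))
  best_obj <- Inf; best_W <- NULL
  for (r in seq_len(nrow(combos))) {
    W <- matrix(0, h, h)
    W[upper.tri(W)] <- as.numeric(combos[r, ])
    W <- W + t(W)
    o <- obj(W)
    if (o < best_obj - 1e-15) { best_obj <- o; best_W <- W }
  }
  list(omega = best_W, objective = best_obj, grid = NULL)
}
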