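#' Neighbor-Joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: repeatedly join the pair (i, j)
#' minimizing \eqn{Q(i,j) = (n-2) d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}},
#' with pendant branch lengths from the standard two-point formulas and the
#' new node's distances by the reduction formula. On an additive matrix the
#' generating tree is recovered exactly. Q ties are broken by the
#' lexicographically smallest (sorted) label pair so results are
#' deterministic. Negative branch lengths (possible on non-additive input)
#' are clamped to zero; the number clamped is recorded in the `clamped`
#' attribute.
#'
#' @param d a `wdf_dist`, `dist`, or symmetric numeric matrix with dimnames
#'   (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  D <- dist_input(d)
  n <- nrow(D)
  if (n < 3L) stop("Neighbor-Joining needs at least 3 taxa")
  labels <- rownames(D)
  tips <- seq_len(n)
  next_node <- 2L * n - 2L              # internal ids count down from 2n-2
  node_of <- tips                       # phylo node id of each active cluster
  act_lab <- labels                     # current label of each active cluster
  edges <- matrix(0L, 0L, 2L); lens <- numeric(0); clamped <- 0L
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    if (len < 0) { clamped <<- clamped + 1L; len <- 0 }
    lens <<- c(lens, len)
  }
  while (nrow(D) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(act_lab[ij[1]], act_lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    u <- next_node; next_node <- next_node - 1L
    add_edge(u, node_of[i], li)
    add_edge(u, node_of[j], lj)
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    newlab <- paste0("(", min(act_lab[i], act_lab[j]), ")")
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], newlab)
    node_of <- c(node_of[keep], u)
    act_lab <- c(act_lab[keep], newlab)
    D <- D2
  }
  # final three clusters join at one trifurcating node
  u <- n + 1L
  l1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  l2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  l3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  add_edge(u, node_of[1L], l1)
  add_edge(u, node_of[2L], l2)
  add_edge(u, node_of[3L], l3)
  tr <- structure(list(edge = edges, edge.length = lens,
                       tip.label = labels, Nnode = n - 2L),
                  class = "phylo", order = NULL)
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "clamped") <- clamped
  tr
}

#' Average-linkage (UPGMA) dendrogram
#'
#' Agglomerates the closest pair, replacing it by a cluster whose distance to
#' every other cluster is the size-weighted arithmetic mean (the classical
#' UPGMA update), so merge heights are non-decreasing on any proper
#' dissimilarity. Ties are broken by the lexicographically smallest label
#' pair. Ultrametric edge lengths are height differences; two leaves at
#' distance d merge at height d/2.
#'
#' @param d a `wdf_dist`, `dist`, or symmetric matrix with dimnames (>= 2).
#' @return A rooted ultrametric `ape::phylo` tree with a `heights` attribute
#'   (merge heights in order).
#' @export
average_linkage <- function(d) {
  D <- dist_input(d)
  n <- nrow(D)
  if (n < 2L) stop("average_linkage needs at least 2 profiles")
  labels <- rownames(D)
  node_of <- seq_len(n); height_of <- numeric(n); size <- rep(1L, n)
  act_lab <- labels
  next_node <- 2L * n - 1L
  edges <- matrix(0L, 0L, 2L); lens <- numeric(0); heights <- numeric(0)
  while (nrow(D) > 1L) {
    m <- nrow(D)
    Dm <- D; diag(Dm) <- Inf
    dmin <- min(Dm)
    cand <- which(Dm - dmin <= 1e-12 * max(1, dmin), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij)
      paste(sort(c(act_lab[ij[1]], act_lab[ij[2]])), collapse = "\r"))
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    h <- D[i, j] / 2
    heights <- c(heights, h)
    u <- next_node; next_node <- next_node - 1L
    edges <- rbind(edges, c(u, node_of[i]), c(u, node_of[j]))
    lens <- c(lens, max(0, h - height_of[i]), max(0, h - height_of[j]))
    du <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    newlab <- min(act_lab[i], act_lab[j])
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], newlab)
    node_of <- c(node_of[keep], u)
    height_of <- c(height_of[keep], h)
    size <- c(size[keep], size[i] + size[j])
    act_lab <- c(act_lab[keep], newlab)
    D <- D2
  }
  # internal ids were assigned 2n-1 down to n+1, so the root (created last)
  # is already n+1 as the phylo convention expects
  tr <- structure(list(edge = edges, edge.length = lens,
                       tip.label = labels, Nnode = n - 1L),
                  class = "phylo", order = NULL)
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "heights") <- heights
  tr
}

#' @noRd
dist_input <- function(d) {
  if (inherits(d, "wdf_dist")) D <- d$d
  else if (inherits(d, "dist")) D <- as.matrix(d)
  else D <- as.matrix(d)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("S", seq_len(nrow(D)))
  D
}

#' Newick serialization
#'
#' Writes branch lengths with six decimal places; labels containing spaces
#' are single-quoted. The output round-trips through `ape::read.tree`.
#'
#' @param tree an `ape::phylo`.
#' @param digits decimal places for branch lengths.
#' @return Newick string terminated by `;`.
#' @export
to_newick <- function(tree, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  qlab <- function(x) if (grepl("[][ ,;:()]", x)) paste0("'", x, "'") else x
  fmt <- function(len) formatC(len, format = "f", digits = digits)
  rec <- function(node, len) {
    body <- if (node <= n) qlab(tree$tip.label[[node]]) else {
      eidx <- kids[[as.character(node)]]
      paste0("(", paste(vapply(eidx, function(e)
        rec(tree$edge[e, 2], tree$edge.length[[e]]), character(1)),
        collapse = ","), ")")
    }
    if (is.na(len)) body else paste0(body, ":", fmt(len))
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[[1L]]
  paste0(rec(root, NA_real_), ";")
}

#' Leaf bipartitions of a tree's internal edges
#'
#' Each internal edge of an unrooted tree splits the leaves in two; the split
#' is canonicalized as the sorted side *not* containing the alphabetically
#' first label, keyed as a `|`-joined string. These keys identify clusters
#' across bootstrap replicates. Trivial splits (single leaf or all leaves)
#' are dropped.
#'
#' @param tree an `ape::phylo`.
#' @return Named list of sorted character vectors; names are the keys.
#' @export
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[[1L]]
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  below <- function(node) {
    if (node <= n) return(tree$tip.label[[node]])
    unlist(lapply(kids[[as.character(node)]],
                  function(e) below(tree$edge[e, 2])))
  }
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next
    side <- below(child)
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    side <- sort(side)
    out[[paste(side, collapse = "|")]] <- side
  }
  out
}
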