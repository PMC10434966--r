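## Native Markov Cluster (MCL) algorithm on sparse column-stochastic
## matrices: alternate expansion (matrix power) and inflation
## (element-wise power + column re-normalization) until the flow matrix
## stops changing, then read clusters off the attractor structure.

#' MCL parameter set
#'
#' @param inflation inflation exponent r > 1; default 2 (the algorithm's
#'   standard default).
#' @param expansion expansion power e >= 2; default 2.
#' @param prune entries below this value are zeroed before each column
#'   re-normalization; default 1e-5.
#' @param max_iter iteration cap; default 100.
#' @param tol convergence tolerance on the maximum absolute entry change;
#'   default 1e-8.
#' @return List of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 2, expansion = 2L, prune = 1e-5,
                       max_iter = 100L, tol = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2, prune >= 0, max_iter >= 1,
            tol > 0)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune = prune, max_iter = as.integer(max_iter), tol = tol),
            class = "mcl_params")
}

#' One inflation + re-normalization step
#'
#' Raises every entry of a column-stochastic matrix to the power `r`,
#' zeroes entries below `prune`, and re-normalizes each column to sum 1.
#' A column emptied by pruning is restored as a self-loop-only column.
#'
#' @param m column-stochastic matrix (base or `Matrix` sparse).
#' @param r inflation exponent (r = 1 leaves the matrix unchanged).
#' @param prune pruning threshold applied before re-normalization.
#' @return Column-stochastic matrix of the same class family.
#' @export
inflate_normalize_step <- function(m, r, prune = 0) {
  m <- methods::as(m, "CsparseMatrix")
  m@x <- m@x^r
  if (prune > 0) m@x[m@x < prune] <- 0
  m <- Matrix::drop0(m)
  cs <- Matrix::colSums(m)
  empty <- which(cs == 0)
  if (length(empty)) {
    m[cbind(empty, empty)] <- 1
    cs[empty] <- 1
  }
  m %*% Matrix::Diagonal(x = 1 / cs)
}

#' Run Markov clustering on a hypernetwork
#'
#' Adds a self-loop to every node (weight = the node's maximum incident
#' edge weight), column-normalizes the adjacency matrix, and alternates
#' expansion and inflation until convergence. Clusters are read off the
#' attractor structure of the limit matrix; every node is assigned to
#' exactly one cluster (a node reached by several attractor systems goes
#' to the one holding most of its flow, ties to the cluster with the
#' lexicographically smallest member).
#'
#' @param net a `hypernetwork` (from [build_hypernetwork()]), or a data
#'   frame of edges with columns `from`, `to`, `weight`.
#' @param params an [mcl_params()] set.
#' @return List of clusters, each a sorted character vector of node ids;
#'   clusters ordered by decreasing size, then first member. Attribute
#'   `converged` reports convergence; non-convergence at `max_iter` emits
#'   a warning and clusters are read from the final matrix.
#' @export
run_mcl <- function(net, params = mcl_params()) {
  stopifnot(inherits(params, "mcl_params"))
  edges <- if (inherits(net, "hypernetwork")) net$edges else as.data.frame(net)
  nodes <- if (inherits(net, "hypernetwork")) net$nodes else
    sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  if (n == 0L) return(structure(list(), converged = TRUE))
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  if (any(i == j))
    stop("self-edges are not allowed in the input network", call. = FALSE)
  # symmetric adjacency with self-loops = max incident weight (1 for
  # isolated nodes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = c(edges$weight, edges$weight),
                              dims = c(n, n))
  loop <- apply_max_incident(adj)
  m <- adj + Matrix::Diagonal(x = loop)
  m <- m %*% Matrix::Diagonal(x = 1 / Matrix::colSums(m))
  converged <- FALSE
  for (iter in seq_len(params$max_iter)) {
    m_new <- m
    for (e in seq_len(params$expansion - 1L)) m_new <- m_new %*% m
    m_new <- inflate_normalize_step(m_new, params$inflation, params$prune)
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge in ", params$max_iter,
            " iterations; reading clusters from the final matrix")
  cl <- mcl_extract_clusters(m, nodes, params$prune)
  attr(cl, "converged") <- converged
  cl
}

apply_max_incident <- function(adj) {
  mx <- numeric(nrow(adj))
  a <- methods::as(adj, "TsparseMatrix")
  if (length(a@x)) {
    for (idx in seq_along(a@x)) {
      r <- a@i[idx] + 1L
      if (a@x[idx] > mx[r]) mx[r] <- a@x[idx]
    }
  }
  mx[mx == 0] <- 1
  mx
}

# Read clusters from a (near-)idempotent MCL limit matrix. Attractors are
# nodes with positive diagonal flow; attractors that exchange flow form
# one attractor system; every node joins the system receiving most of its
# column's flow.
mcl_extract_clusters <- function(m, nodes, thr) {
  n <- length(nodes)
  d <- Matrix::diag(m)
  att <- which(d > thr)
  if (!length(att)) att <- seq_len(n)  # degenerate; treat all as attractors
  sub <- m[att, att, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(
    (sub + Matrix::t(sub)) > 0, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership  # attractor -> system
  nsys <- max(comp)
  # order systems by their lexicographically smallest attractor so that
  # tie-breaking is well-defined and input-order independent
  sys_min <- vapply(seq_len(nsys), function(s)
    min(nodes[att[comp == s]]), "")
  sys_rank <- order(sys_min, method = "radix")
  # flow mass from each node's column into each system
  mass <- matrix(0, nsys, n)
  msub <- m[att, , drop = FALSE]
  for (s in seq_len(nsys)) {
    rows <- which(comp == s)
    mass[s, ] <- Matrix::colSums(msub[rows, , drop = FALSE])
  }
  mass <- mass[sys_rank, , drop = FALSE]
  assign <- apply(mass, 2L, which.max)
  # nodes with no flow to any attractor (non-converged edge case) become
  # singletons
  none <- which(apply(mass, 2L, max) == 0)
  clusters <- split(nodes, assign)
  clusters <- lapply(clusters, function(x) sort(setdiff(x, nodes[none])))
  clusters <- clusters[vapply(clusters, length, 1L) > 0L]
  clusters <- c(clusters, lapply(nodes[none], identity))
  clusters <- lapply(clusters, sort)
  first <- vapply(clusters, `[[`, "", 1L)
  sizes <- vapply(clusters, length, 1L)
  clusters <- clusters[order(-sizes, first, method = "radix")]
  names(clusters) <- NULL
  clusters
}
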