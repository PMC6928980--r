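# Two-group clustering of sites (rows) and hours (columns of the
# transposed matrix): Euclidean distances, complete-linkage and DIANA
# trees, k-means / PAM partitions, classical MDS, and Mann-Whitney ranking
# of the hours that discriminate the two site clusters.

CLUSTER_METHODS <- c("hierarchical", "diana", "kmeans", "pam")

#' Euclidean distances between rows or columns
#'
#' @param matrix a `scaled_matrix` (or plain numeric matrix).
#' @param orientation `"rows"` (sites) or `"columns"` (hours, i.e. the
#'   transposed matrix).
#' @return a `stats::dist` object with labels.
#' @export
euclidean_distances <- function(matrix, orientation = c("rows", "columns")) {
  orientation <- match.arg(orientation)
  m <- unclass(matrix)
  stopifnot(is.matrix(m))
  if (orientation == "columns") m <- t(m)
  if (nrow(m) < 2) stop("need at least 2 items to compute distances")
  dist(m, method = "euclidean")
}

#' Complete-linkage agglomerative clustering
#'
#' Starts from singletons and repeatedly merges the two clusters with the
#' smallest maximum inter-cluster distance; merge heights are
#' non-decreasing.
#'
#' @param d a `dist` object.
#' @return an `hclust` tree.
#' @export
agglomerative_complete <- function(d) {
  stopifnot(inherits(d, "dist"), attr(d, "Size") >= 2)
  hclust(d, method = "complete")
}

#' Divisive analysis (DIANA) clustering
#'
#' Top-down hierarchy: the cluster with the largest diameter is split by
#' seeding a splinter group with the most dissimilar item and letting
#' items defect while their average dissimilarity favours the splinter
#' side. Backed by `cluster::diana`.
#'
#' @param d a `dist` object.
#' @return a `cluster::diana` tree (convertible with `as.hclust`).
#' @export
diana_cluster <- function(d) {
  stopifnot(inherits(d, "dist"), attr(d, "Size") >= 2)
  cluster::diana(d, diss = TRUE)
}

#' Cut a hierarchical tree into k groups
#'
#' @param tree an `hclust` or `diana`/`agnes` tree.
#' @param k number of clusters, 1..n.
#' @return An object of class `cluster_outcome`: list with `method`, `k`,
#'   `labels` (named integer vector, cluster ids 1..k), `tree`.
#' @export
cut_k <- function(tree, k) {
  h <- if (inherits(tree, "hclust")) tree else stats::as.hclust(tree)
  n <- length(h$order)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  labels <- cutree(h, k = k)
  method <- if (inherits(tree, "diana")) "diana" else "hierarchical"
  structure(list(method = method, k = as.integer(k), labels = labels,
                 tree = tree),
            class = "cluster_outcome")
}

#' k-means or PAM partition into k groups
#'
#' k-means runs Lloyd iterations from 25 seeded random initializations
#' (keeping the lowest within-cluster sum of squares, up to 300
#' iterations); PAM runs BUILD + SWAP on the distance matrix and is
#' deterministic. Same seed, same labels.
#'
#' @param x a `scaled_matrix` / numeric matrix (k-means) or either a
#'   matrix or `dist` (PAM).
#' @param method `"kmeans"` or `"pam"`.
#' @param k number of clusters (2..n).
#' @param seed integer seed for the k-means restarts.
#' @return a `cluster_outcome` (no tree).
#' @export
partition_cluster <- function(x, method = c("kmeans", "pam"), k, seed = 1) {
  method <- match.arg(method)
  if (method == "kmeans") {
    m <- unclass(x)
    stopifnot(is.matrix(m))
    if (k > nrow(m)) stop("k exceeds the number of items")
    fit <- with_seed(seed, kmeans(m, centers = k, nstart = 25,
                                  iter.max = 300, algorithm = "Lloyd"))
    labels <- fit$cluster
    names(labels) <- rownames(m)
  } else {
    d <- if (inherits(x, "dist")) x else dist(unclass(x))
    if (k > attr(d, "Size")) stop("k exceeds the number of items")
    fit <- cluster::pam(d, k = k, diss = TRUE)
    labels <- fit$clustering
  }
  structure(list(method = method, k = as.integer(k), labels = labels,
                 tree = NULL),
            class = "cluster_outcome")
}

# one entry point used by the validation loops
cluster_with_method <- function(method, scaled, d = NULL, k = 2, seed = 1) {
  if (is.null(d)) d <- dist(unclass(scaled))
  switch(method,
         hierarchical = cut_k(agglomerative_complete(d), k),
         diana = cut_k(diana_cluster(d), k),
         kmeans = partition_cluster(scaled, "kmeans", k, seed),
         pam = partition_cluster(d, "pam", k),
         stop("unknown clustering method: ", method))
}

#' Newick serialization of a hierarchical tree
#'
#' @param tree an `hclust` / `diana` tree.
#' @return a single Newick string with branch lengths derived from merge
#'   heights.
#' @export
tree_to_newick <- function(tree) {
  h <- if (inherits(tree, "hclust")) tree else stats::as.hclust(tree)
  ape::write.tree(ape::as.phylo(h))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distances, eigendecomposes, and returns the
#' top-`dims` coordinates. Explained variance per dimension is the
#' eigenvalue over the sum of positive eigenvalues, in percent.
#'
#' @param d a `dist` object.
#' @param dims number of dimensions (default 2). If fewer positive
#'   eigenvalues exist the result is truncated with a warning.
#' @return list with `coordinates` (n x dims matrix), `explained_pct`
#'   (length dims), `eigenvalues`.
#' @export
classical_mds <- function(d, dims = 2) {
  stopifnot(inherits(d, "dist"), dims >= 1)
  fit <- cmdscale(d, k = min(dims, attr(d, "Size") - 1), eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12 * max(abs(fit$eig))]
  got <- ncol(fit$points)
  if (got < dims)
    warning("only ", got, " positive dimensions available; truncated")
  keep <- min(dims, got, length(pos))
  coords <- fit$points[, seq_len(keep), drop = FALSE]
  colnames(coords) <- paste0("dim", seq_len(keep))
  list(coordinates = coords,
       explained_pct = 100 * fit$eig[seq_len(keep)] / sum(pos),
       eigenvalues = fit$eig)
}

#' Explained-variance summary of an MDS solution
#'
#' @param mds a [classical_mds()] result, or directly a numeric vector of
#'   per-dimension explained percentages.
#' @return data frame with one row per dimension plus a `total` row.
#' @export
mds_variance_summary <- function(mds) {
  pct <- if (is.numeric(mds)) mds else mds$explained_pct
  stopifnot(all(pct >= 0), sum(pct) <= 100 + 1e-9)
  data.frame(dimension = c(paste0("dim", seq_along(pct)), "total"),
             explained_pct = round(c(pct, sum(pct)), 1))
}

#' Rank hours by between-cluster Mann-Whitney differences
#'
#' For every hour of day, a two-sided Mann-Whitney U test (normal
#' approximation with tie correction) compares the sites of the two
#' clusters; hours are ordered by decreasing |z| (equivalently increasing
#' p). The top hours are the candidates for the traffic-flow parameter x.
#'
#' @param shm a [build_site_hour_matrix()] result (unscaled medians).
#' @param outcome a 2-cluster `cluster_outcome` on the same sites, each
#'   cluster with at least 2 sites.
#' @return data frame ordered by rank: `hour`, `U`, `z`, `p`, `rank`.
#' @export
mannwhitney_hour_ranking <- function(shm, outcome) {
  stopifnot(inherits(shm, "site_hour_matrix"),
            inherits(outcome, "cluster_outcome"), outcome$k == 2)
  labels <- outcome$labels[shm$site_ids]
  if (any(table(labels) < 2)) stop("each cluster needs at least 2 sites")
  res <- t(vapply(0:23, function(h) {
    x <- shm$values[labels == 1, h + 1]
    y <- shm$values[labels == 2, h + 1]
    mann_whitney_z(x, y)
  }, numeric(3)))
  out <- data.frame(hour = 0:23, U = res[, 1], z = res[, 2], p = res[, 3])
  out <- out[order(-abs(out$z), out$p), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# U statistic of x vs y, tie-corrected normal z, two-sided p
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (u - mu) / sqrt(sigma2) else 0
  c(U = u, z = z, p = 2 * pnorm(-abs(z)))
}
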