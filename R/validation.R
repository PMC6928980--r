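# Seven-measure cluster validation: three internal measures
# (connectivity, silhouette width, Dunn index) and four stability
# measures computed by leave-one-column-out reclustering (APN, AD, ADM,
# FOM), plus mean-rank aggregation to select the best method.

#' Internal validation measures of a partition
#'
#' * connectivity: for each item, the j-th of its `neighborhood` nearest
#'   neighbours contributes 1/j when it sits in another cluster (0 is
#'   perfect, smaller is better);
#' * silhouette width: mean of (b - a)/max(a, b) with a = mean
#'   within-cluster distance and b = smallest mean distance to another
#'   cluster; items in singleton clusters contribute 0 by convention;
#' * Dunn index: smallest between-cluster item-pair distance over the
#'   largest within-cluster diameter (larger is better).
#'
#' All three are invariant under relabeling of the clusters.
#'
#' @param outcome a `cluster_outcome` (k >= 2) or a bare label vector.
#' @param d the `dist` the partition was computed on.
#' @param neighborhood neighbourhood size for connectivity (default 10).
#' @return list with `connectivity`, `silhouette`, `dunn`.
#' @export
internal_validation <- function(outcome, d, neighborhood = 10) {
  labels <- if (inherits(outcome, "cluster_outcome")) outcome$labels else outcome
  if (length(unique(labels)) < 2) stop("need k >= 2 clusters")
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(length(labels) == n)
  nb <- min(neighborhood, n - 1)

  conn <- 0
  for (i in seq_len(n)) {
    nn <- order(dm[i, -i])            # indices within the reduced vector
    others <- seq_len(n)[-i][nn]
    mism <- labels[others[seq_len(nb)]] != labels[i]
    conn <- conn + sum((1 / seq_len(nb))[mism])
  }

  sil <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)       # singleton convention
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(dm[i, labels == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))

  inter <- min(dm[outer(labels, labels, "!=")])
  intra <- max(vapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2) 0 else max(dm[idx, idx])
  }, numeric(1)))
  dunn <- if (intra > 0) inter / intra else Inf

  list(connectivity = conn, silhouette = mean(sil), dunn = dunn)
}

#' Stability validation by leave-one-column-out reclustering
#'
#' Each data column is removed in turn and the reduced data re-clustered
#' with the same method and k. With C_i0 the full-data cluster (as a set
#' of items) of item i and C_il its cluster after removing column l:
#' * APN: mean of 1 - |C_il intersect C_i0| / |C_i0| (0 = perfectly stable);
#' * AD: mean of the average full-data distance between items of C_i0 and
#'   items of C_il;
#' * ADM: mean distance between the centroids of C_il and C_i0 in
#'   full-data coordinates;
#' * FOM: mean over columns of the root mean squared deviation of the
#'   removed column from its reduced-clustering cluster means, times the
#'   adjustment factor sqrt(n/(n - k)).
#'
#' @param scaled the `scaled_matrix` (items x columns) being clustered.
#' @param method one of `"hierarchical"`, `"diana"`, `"kmeans"`, `"pam"`.
#' @param k number of clusters.
#' @param seed seed forwarded to stochastic methods (k-means restarts).
#' @return list with `apn`, `ad`, `adm`, `fom`.
#' @export
stability_validation <- function(scaled, method, k, seed = 1) {
  x <- unclass(scaled)
  stopifnot(is.matrix(x), ncol(x) >= 3)
  method <- match.arg(method, CLUSTER_METHODS)
  n <- nrow(x)
  p <- ncol(x)
  dfull <- dist(x)
  dm <- as.matrix(dfull)
  full <- cluster_with_method(method, x, dfull, k, seed)$labels
  full_sets <- lapply(seq_len(n), function(i) which(full == full[i]))

  apn <- ad <- adm <- 0
  fom <- numeric(p)
  for (l in seq_len(p)) {
    xr <- x[, -l, drop = FALSE]
    red <- cluster_with_method(method, xr, dist(xr), k, seed)$labels
    red_sets <- lapply(seq_len(n), function(i) which(red == red[i]))
    for (i in seq_len(n)) {
      s0 <- full_sets[[i]]
      sl <- red_sets[[i]]
      apn <- apn + 1 - length(intersect(sl, s0)) / length(s0)
      ad <- ad + mean(dm[s0, sl])
      c0 <- colMeans(x[s0, , drop = FALSE])
      cl <- colMeans(x[sl, , drop = FALSE])
      adm <- adm + sqrt(sum((c0 - cl)^2))
    }
    cl_means <- tapply(x[, l], red, mean)
    fom[l] <- sqrt(mean((x[, l] - cl_means[as.character(red)])^2)) *
      sqrt(n / (n - k))
  }
  denom <- n * p
  list(apn = apn / denom, ad = ad / denom, adm = adm / denom,
       fom = mean(fom))
}

#' Score several clustering methods with all seven measures
#'
#' @param scaled the `scaled_matrix` to cluster.
#' @param k number of clusters (default 2).
#' @param methods methods to score (default all four implemented).
#' @param neighborhood connectivity neighbourhood size.
#' @param seed seed for stochastic methods.
#' @return An object of class `validation_report`: list with `report`
#'   (data frame, one row per method, seven measure columns) and
#'   `outcomes` (the full-data `cluster_outcome` per method).
#' @export
validation_report <- function(scaled, k = 2, methods = CLUSTER_METHODS,
                              neighborhood = 10, seed = 1) {
  stopifnot(length(methods) >= 1)
  d <- dist(unclass(scaled))
  outcomes <- list()
  rows <- lapply(methods, function(m) {
    out <- cluster_with_method(m, scaled, d, k, seed)
    outcomes[[m]] <<- out
    iv <- internal_validation(out, d, neighborhood)
    sv <- stability_validation(scaled, m, k, seed)
    data.frame(method = m, connectivity = iv$connectivity,
               silhouette = iv$silhouette, dunn = iv$dunn,
               apn = sv$apn, ad = sv$ad, adm = sv$adm, fom = sv$fom)
  })
  structure(list(report = do.call(rbind, rows), outcomes = outcomes,
                 k = k, neighborhood = neighborhood, seed = seed),
            class = "validation_report")
}

#' Select the best clustering method by mean rank over the seven measures
#'
#' Connectivity, APN, AD, ADM and FOM rank smaller-is-better; silhouette
#' and Dunn larger-is-better. The method with the smallest mean rank wins;
#' ties go to the larger silhouette. Presentation order does not matter.
#'
#' @param report a [validation_report()] or its `report` data frame.
#' @return list with `selected` (method name), `ranks` (method x measure
#'   data frame), `aggregate` (named mean ranks).
#' @export
rank_methods <- function(report) {
  df <- if (inherits(report, "validation_report")) report$report else report
  stopifnot(nrow(df) >= 2)
  lower <- c("connectivity", "apn", "ad", "adm", "fom")
  higher <- c("silhouette", "dunn")
  ranks <- sapply(c(lower, higher), function(m) {
    v <- df[[m]]
    if (m %in% higher) v <- -v
    rank(v, ties.method = "average")
  })
  rownames(ranks) <- df$method
  aggregate <- rowMeans(ranks)
  best <- which(aggregate == min(aggregate))
  if (length(best) > 1) best <- best[which.max(df$silhouette[best])]
  list(selected = df$method[best],
       ranks = as.data.frame(ranks),
       aggregate = aggregate)
}
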