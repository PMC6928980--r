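test_that("euclidean_distances works on rows and columns", {
  m <- rbind(a = c(0, 0, 0, 0), b = c(3, 4, 0, 0))
  d <- euclidean_distances(m, "rows")
  expect_equal(as.numeric(d), 5)
  # identical rows have distance 0; symmetry on random input
  m2 <- rbind(x = 1:4, y = 1:4)
  expect_equal(as.numeric(euclidean_distances(m2)), 0)
  r <- matrix(rnorm(40), 8, 5)
  dm <- as.matrix(euclidean_distances(r, "rows"))
  expect_equal(dm, t(dm))
  expect_equal(dim(as.matrix(euclidean_distances(r, "columns"))), c(5, 5))
  expect_error(euclidean_distances(m[1, , drop = FALSE]), "at least 2")
})

test_that("complete linkage reproduces the hand-run {0,1,10,11} example", {
  m <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("p0", "p1", "p10", "p11"), NULL))
  d <- euclidean_distances(m, "rows")
  tree <- agglomerative_complete(d)
  expect_true(all(diff(tree$height) >= 0))
  expect_equal(max(tree$height), 11)
  out <- cut_k(tree, 2)
  expect_equal(unname(out$labels[c("p0", "p1")]),
               rep(out$labels[["p0"]], 2))
  expect_equal(unname(out$labels[c("p10", "p11")]),
               rep(out$labels[["p10"]], 2))
  expect_false(out$labels[["p0"]] == out$labels[["p10"]])

  # two items: a single merge at their distance
  t2 <- agglomerative_complete(dist(c(2, 9)))
  expect_equal(t2$height, 7)
})

test_that("diana_cluster reproduces the hand-run example and recovers groups", {
  m <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("p0", "p1", "p10", "p11"), NULL))
  out <- cut_k(diana_cluster(euclidean_distances(m, "rows")), 2)
  expect_equal(unname(out$labels[c("p0", "p1")]), c(1, 1))
  expect_equal(unname(out$labels[c("p10", "p11")]), c(2, 2))
  expect_identical(out$method, "diana")

  # simulation oracle: separation >> spread recovers generating labels
  with_seed(99, {
    for (rep in 1:5) {
      truth <- rep(1:2, each = 10)
      x <- matrix(rnorm(20 * 4, mean = rep(c(0, 20), each = 10)), 20, 4)
      rownames(x) <- paste0("i", 1:20)
      lab <- cut_k(diana_cluster(dist(x)), 2)$labels
      expect_equal(adjusted_rand_index(lab, truth), 1)
    }
  })
})

test_that("cut_k spans k = 1 .. n", {
  d <- dist(c(0, 1, 10, 11))
  tree <- agglomerative_complete(d)
  expect_equal(unname(cut_k(tree, 1)$labels), rep(1, 4))
  expect_equal(sort(unname(cut_k(tree, 4)$labels)), 1:4)
  expect_error(cut_k(tree, 5), "k must be")
  expect_error(cut_k(tree, 0), "k must be")
})

test_that("kmeans and pam partition well-separated pairs deterministically", {
  m <- rbind(a = c(0, 0), b = c(0.5, 0), c = c(30, 0), d = c(30.5, 0))
  for (method in c("kmeans", "pam")) {
    out <- partition_cluster(m, method, k = 2, seed = 5)
    expect_equal(out$labels[["a"]], out$labels[["b"]])
    expect_equal(out$labels[["c"]], out$labels[["d"]])
    expect_false(out$labels[["a"]] == out$labels[["c"]])
    # determinism under a fixed seed
    expect_identical(out$labels,
                     partition_cluster(m, method, k = 2, seed = 5)$labels)
  }
  # k = n items -> singletons
  expect_equal(sort(unname(partition_cluster(m, "kmeans", 4, 1)$labels)), 1:4)
  expect_error(partition_cluster(m, "kmeans", 5, 1), "exceeds")
})

test_that("classical_mds preserves distances and reports variance", {
  with_seed(8, {
    x <- matrix(rnorm(20), 10, 2)
    d <- dist(x)
    fit <- classical_mds(d, dims = 2)
    expect_equal(as.numeric(dist(fit$coordinates)), as.numeric(d),
                 tolerance = 1e-9)
    expect_true(all(fit$explained_pct >= 0))
    expect_lte(sum(fit$explained_pct), 100 + 1e-9)
  })
  # collinear points: dimension 1 explains 100%
  fit1 <- classical_mds(dist(cbind(1:5, 2 * (1:5))), dims = 2)
  expect_equal(fit1$explained_pct[1], 100, tolerance = 1e-9)

  s <- mds_variance_summary(c(68.4, 19.9))
  expect_equal(s$explained_pct[s$dimension == "total"], 88.3)
})

test_that("tree_to_newick emits parseable Newick with heights", {
  d <- dist(c(0, 1, 10, 11))
  nwk <- tree_to_newick(agglomerative_complete(d))
  expect_match(nwk, "^\\(.*\\);$")
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph), 4)
})

test_that("mannwhitney_hour_ranking orders hours by separation", {
  # build a matrix where hour 5 separates clusters completely, hour 10
  # is identical across clusters, others are noise
  with_seed(77, {
    n <- 12
    vals <- matrix(runif(n * 24, 40, 60), n, 24)
    labels <- rep(1:2, each = n / 2)
    vals[labels == 1, 6] <- runif(n / 2, 0, 10)
    vals[labels == 2, 6] <- runif(n / 2, 90, 100)
    vals[, 11] <- 50
    colnames(vals) <- sprintf("hour_%02d", 0:23)
    rownames(vals) <- paste0("S", 1:n)
    shm <- structure(list(site_ids = rownames(vals), road_classes = NULL,
                          values = vals, mad = vals * 0,
                          rejected = character(0)),
                     class = "site_hour_matrix")
    out <- structure(list(method = "diana", k = 2L,
                          labels = setNames(labels, rownames(vals)),
                          tree = NULL), class = "cluster_outcome")
    rk <- mannwhitney_hour_ranking(shm, out)
    expect_equal(rk$hour[1], 5)            # complete separation: U = 0
    expect_equal(rk$U[rk$hour == 5], 0)
    # the constant hour has |z| = 0 and ties for the last rank
    expect_equal(abs(rk$z[rk$hour == 10]), 0)
    expect_equal(min(abs(rk$z)), 0)
    expect_equal(rk$U[rk$hour == 10], prod(table(labels)) / 2)
  })
})

test_that("Mann-Whitney z/p agree with the exact enumeration oracle", {
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1 (2/20)
  expect_equal(oracle_mw_exact_p(1:3, 4:6), 0.1)
  # the normal-approximation machinery agrees with the oracle in rank
  # ordering across random small samples
  with_seed(3, {
    for (i in 1:20) {
      x <- sample(1:100, 4)
      y <- sample(1:100, 5)
      res <- noisir:::mann_whitney_z(x, y)
      p_exact <- oracle_mw_exact_p(x, y)
      # the normal approximation tracks the exact enumeration p
      expect_lt(abs(res[["p"]] - p_exact), 0.2)
      expect_gte(res[["U"]], 0)
      expect_lte(res[["U"]], 20)
    }
    # and the tie-corrected p matches wilcox.test's normal approximation
    x <- c(3, 7, 7, 12, 15); y <- c(6, 7, 14, 18, 20, 22)
    res <- noisir:::mann_whitney_z(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = FALSE))
    expect_equal(res[["p"]], ref$p.value, tolerance = 1e-12)
    expect_equal(res[["U"]], unname(ref$statistic))
  })
})
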