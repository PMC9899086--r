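test_that("EM recovers well-separated component means", {
  set.seed(1)
  truth <- rbind(c(0, 0), c(1, 0), c(0, 1))
  cl <- make_clusters(truth, 20, 0.02)
  m <- fit_gmm(cl$x, 3, seed = 2)
  # each fitted mean within 0.02 of a distinct true mean
  d <- as.matrix(stats::dist(rbind(m$means, truth)))[1:3, 4:6]
  matched <- apply(d, 1, which.min)
  expect_equal(sort(unname(matched)), 1:3)
  expect_true(all(apply(d, 1, min) < 0.02))
  expect_true(abs(sum(m$weights) - 1) < 1e-12)
})

test_that("coincident points converge to the regularization covariance", {
  x <- matrix(rep(c(0.3, 0.7), each = 40), ncol = 2)
  m <- fit_gmm(x, 2, seed = 1, n_init = 2, reg = 1e-6)
  for (j in 1:2) {
    expect_equal(m$covariances[, , j], diag(1e-6, 2), tolerance = 1e-8)
  }
  expect_true(all(is.finite(m$loglik_trace)))
})

test_that("the log-likelihood trace is non-decreasing on arbitrary inputs", {
  set.seed(33)
  for (i in 1:10) {
    x <- matrix(rnorm(60), ncol = 2)
    m <- fit_gmm(x, sample(2:4, 1), seed = i, n_init = 3)
    expect_true(all(diff(m$loglik_trace) >= -1e-8))
  }
})

test_that("posteriors are proper and labels are deterministic in the seed", {
  set.seed(5)
  cl <- make_clusters(rbind(c(0, 0), c(3, 3)), 15, 0.3)
  m1 <- fit_gmm(cl$x, 2, seed = 7)
  m2 <- fit_gmm(cl$x, 2, seed = 7)
  expect_identical(m1$means, m2$means)
  expect_identical(m1$log_likelihood, m2$log_likelihood)
  post <- gmm_posterior(m1, cl$x)
  expect_equal(rowSums(post), rep(1, nrow(cl$x)))
  expect_equal(gmm_labels(m1, cl$x), max.col(post))
})

test_that("silhouette separates the canonical cases", {
  set.seed(21)
  far <- make_clusters(rbind(c(0, 0), c(10, 0)), 20, 0.1)
  expect_gt(silhouette_mean(far$x, far$labels), 0.95)
  mixed <- make_clusters(rbind(c(0, 0), c(0, 0)), 30, 0.5)
  expect_lt(abs(silhouette_mean(mixed$x, mixed$labels)), 0.1)
})

test_that("silhouette equals the independent pairwise-distance oracle", {
  skip_if_not_installed("cluster")
  set.seed(14)
  x <- matrix(rnorm(40), ncol = 2) # 20 fixed points
  lab <- rep(1:3, length.out = 20)
  ours <- silhouette_mean(x, lab)
  ref <- mean(cluster::silhouette(lab, stats::dist(x))[, "sil_width"])
  expect_equal(as.numeric(ours), ref, tolerance = 1e-9)
  expect_error(silhouette_mean(x, rep(1, 20)), "two clusters")
})

test_that("singleton clusters contribute zero silhouette", {
  x <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  s <- silhouette_mean(x, c(1, 1, 2))
  w <- attr(s, "widths")
  expect_equal(w[3], 0)
})

test_that("silhouette-based selection recovers the generative k", {
  set.seed(3)
  cl3 <- make_clusters(rbind(c(0, 0), c(4, 0), c(0, 4)), 12, 0.2)
  r3 <- select_k(cl3$x, 3:5, seed = 11)
  expect_equal(r3$chosen_k, 3L)
  cl5 <- make_clusters(rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4), c(8, 2)),
                       10, 0.2)
  r5 <- select_k(cl5$x, 3:5, seed = 11)
  expect_equal(r5$chosen_k, 5L)
  expect_equal(length(r5$assignments), nrow(cl5$x))
})

test_that("a screen-sized point set (14 drivers) fits cleanly for k up to 5", {
  set.seed(41)
  x <- matrix(rnorm(28, sd = 0.05), ncol = 2) # 14 daytime driver points
  r <- select_k(x, 3:5, seed = 2, n_init = 10)
  expect_true(r$chosen_k %in% 3:5)
  expect_true(all(vapply(r$models, function(m) all(is.finite(m$loglik_trace)),
                         logical(1))))
  # too few points: largest k skipped with warning; all unusable -> error
  expect_warning(select_k(x[1:5, ], 3:5, seed = 2, n_init = 2), "not enough")
  expect_error(suppressWarnings(select_k(x[1:3, ], 3:5, seed = 2)),
               "no candidate")
})

test_that("silhouette and adjusted Rand are invariant to label permutation", {
  skip_if_not_installed("mclust")
  set.seed(6)
  cl <- make_clusters(rbind(c(0, 0), c(3, 0), c(0, 3)), 10, 0.3)
  s1 <- silhouette_mean(cl$x, cl$labels)
  perm <- c(2L, 3L, 1L)[cl$labels]
  expect_equal(as.numeric(s1), as.numeric(silhouette_mean(cl$x, perm)))
  expect_equal(mclust::adjustedRandIndex(cl$labels, perm), 1)
})

test_that("clusters separated by 5 sd are recovered with ARI >= 0.9", {
  skip_if_not_installed("mclust")
  set.seed(27)
  sd0 <- 0.1
  cl <- make_clusters(rbind(c(0, 0), c(5 * sd0 * 10, 0), c(0, 5 * sd0 * 10)),
                      15, sd0)
  m <- fit_gmm(cl$x, 3, seed = 4)
  ari <- mclust::adjustedRandIndex(gmm_labels(m, cl$x), cl$labels)
  expect_gte(ari, 0.9)
})

test_that("fitted means agree with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust)) # Mclust needs its namespace attached
  set.seed(18)
  cl <- make_clusters(rbind(c(0, 0), c(2, 2)), 25, 0.3)
  ours <- fit_gmm(cl$x, 2, seed = 5)
  ref <- mclust::Mclust(cl$x, G = 2, modelNames = "VVV", verbose = FALSE)
  ref_means <- t(ref$parameters$mean)
  d <- as.matrix(stats::dist(rbind(ours$means, ref_means)))[1:2, 3:4]
  expect_true(all(apply(d, 1, min) < 0.05))
})

test_that("cluster ellipses follow the covariance eigenstructure", {
  m <- structure(list(k = 2L,
                      means = rbind(c(0, 0), c(1, 1)),
                      covariances = array(c(diag(0.04, 2), diag(c(4, 1))),
                                          c(2, 2, 2))),
                 class = "damscreen_gmm")
  circ <- cluster_ellipse(m, 1, n_sigma = 2)
  expect_equal(circ$axes, c(0.4, 0.4))
  el <- cluster_ellipse(m, 2, n_sigma = 1)
  expect_equal(el$axes, c(2, 1))
  expect_equal(el$angle %% pi, 0)
  # random SPD matrix vs eigen oracle
  set.seed(2)
  A <- matrix(rnorm(4), 2)
  S <- crossprod(A) + diag(0.1, 2)
  m$covariances[, , 1] <- S
  e <- cluster_ellipse(m, 1, n_sigma = 1.5)
  ev <- eigen(S, symmetric = TRUE)
  expect_equal(e$axes, 1.5 * sqrt(ev$values))
})
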