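# Full-covariance Gaussian mixtures over driver points in
# (delta P(wake), delta P(doze)) space, fitted by EM with k-means++
# seeding and multiple restarts; component count chosen by mean
# silhouette over k in {3, 4, 5}.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.log_sum_exp_rows <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# n x k matrix of component log-densities; closed form in 2-D (the
# screen's delta-P space), Cholesky otherwise
.gmm_log_dens <- function(x, means, covariances) {
  n <- nrow(x); d <- ncol(x); k <- nrow(means)
  out <- matrix(0, n, k)
  if (d == 2L) {
    x1 <- x[, 1L]; x2 <- x[, 2L]
    for (j in seq_len(k)) {
      S <- covariances[, , j]
      det <- S[1L] * S[4L] - S[2L]^2
      dx1 <- x1 - means[j, 1L]; dx2 <- x2 - means[j, 2L]
      quad <- (dx1 * dx1 * S[4L] - 2 * dx1 * dx2 * S[2L] +
                 dx2 * dx2 * S[1L]) / det
      out[, j] <- -0.5 * (2 * log(2 * pi) + log(det) + quad)
    }
  } else {
    for (j in seq_len(k)) {
      R <- chol(covariances[, , j])
      xc <- sweep(x, 2L, means[j, ])
      z <- t(backsolve(R, t(xc), transpose = TRUE))
      out[, j] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) +
                            rowSums(z^2))
    }
  }
  out
}

# k-means++ center seeding
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- colSums((t(x) - centers[1L, ])^2)
    for (j in 2L:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
  }
  centers
}

.gmm_em_once <- function(x, k, reg, tol, max_iter) {
  n <- nrow(x); d <- ncol(x)
  centers <- .kmeanspp_centers(x, k)
  # a few Lloyd iterations sharpen the seeding and cut EM iterations
  km <- tryCatch(suppressWarnings(stats::kmeans(x, centers, iter.max = 10L)),
                 error = function(e) NULL)
  lab <- if (!is.null(km) && length(unique(km$cluster)) == k) {
    km$cluster
  } else {
    max.col(-vapply(seq_len(k),
                    function(j) colSums((t(x) - centers[j, ])^2),
                    numeric(n)))
  }
  centers <- if (!is.null(km) && length(unique(km$cluster)) == k) {
    km$centers
  } else centers
  weights <- pmax(tabulate(lab, k), 1) / sum(pmax(tabulate(lab, k), 1))
  means <- centers
  covariances <- array(0, c(d, d, k))
  pooled <- stats::cov(x) * (n - 1) / n + diag(reg, d)
  for (j in seq_len(k)) {
    xs <- x[lab == j, , drop = FALSE]
    covariances[, , j] <- if (nrow(xs) > d) {
      stats::cov(xs) * (nrow(xs) - 1) / nrow(xs) + diag(reg, d)
    } else pooled
  }
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  prev <- NULL
  for (it in seq_len(max_iter)) {
    la <- .gmm_log_dens(x, means, covariances)
    la <- la + rep(log(weights), each = n)
    lse <- .log_sum_exp_rows(la)
    ll <- sum(lse)
    # the covariance floor makes the M-step slightly inexact; guard the
    # ascent: a non-increasing step means we are at the floor's optimum
    if (!is.null(prev) && (!is.finite(ll) || ll < ll_prev)) {
      weights <- prev$weights; means <- prev$means
      covariances <- prev$covariances
      converged <- TRUE
      break
    }
    trace <- c(trace, ll)
    resp <- exp(la - lse)
    if (is.finite(ll) && abs(ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- ll
    prev <- list(weights = weights, means = means, covariances = covariances)
    nk <- colSums(resp)
    weights <- pmax(nk, 1e-12) / sum(pmax(nk, 1e-12))
    for (j in seq_len(k)) {
      if (nk[j] < 1e-8) next # dying component: freeze its parameters
      rj <- resp[, j]
      if (d == 2L) {
        m1 <- sum(rj * x[, 1L]) / nk[j]; m2 <- sum(rj * x[, 2L]) / nk[j]
        means[j, ] <- c(m1, m2)
        dx1 <- x[, 1L] - m1; dx2 <- x[, 2L] - m2
        covariances[1L, 1L, j] <- sum(rj * dx1 * dx1) / nk[j] + reg
        covariances[2L, 2L, j] <- sum(rj * dx2 * dx2) / nk[j] + reg
        covariances[1L, 2L, j] <- covariances[2L, 1L, j] <-
          sum(rj * dx1 * dx2) / nk[j]
      } else {
        means[j, ] <- crossprod(rj, x) / nk[j]
        xc <- sweep(x, 2L, means[j, ])
        covariances[, , j] <- crossprod(xc * rj, xc) / nk[j] + diag(reg, d)
      }
    }
  }
  list(weights = weights, means = means, covariances = covariances,
       log_likelihood = trace[length(trace)], loglik_trace = trace,
       converged = converged, n_iter = length(trace))
}

#' Fit a full-covariance Gaussian mixture by EM
#'
#' k-means++ seeding, `n_init` independent restarts (best restart by final
#' log-likelihood kept), covariances regularized by `reg * I` so degenerate
#' inputs (e.g. coincident points) stay positive definite. The returned
#' per-iteration log-likelihood trace is non-decreasing.
#'
#' @param x Numeric matrix, one row per point (the screen uses 2-D
#'   delta-P coordinates); must have more rows than `k`.
#' @param k Number of mixture components (>= 1).
#' @param seed Integer seed; identical seed + input give an identical model.
#' @param n_init Number of restarts.
#' @param reg Covariance ridge added to every component.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @return Object of class `damscreen_gmm`: `k`, `weights`, `means`
#'   (k x d), `covariances` (d x d x k), `log_likelihood`, `loglik_trace`,
#'   `converged`, `n_iter`, `seed`.
#' @export
fit_gmm <- function(x, k, seed = 1L, n_init = 20L, reg = 1e-6,
                    tol = 1e-6, max_iter = 500L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (nrow(x) <= k) stop("need more points than mixture components",
                         call. = FALSE)
  best <- NULL
  .with_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- .gmm_em_once(x, k, reg = reg, tol = tol, max_iter = max_iter)
      if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
    }
  })
  structure(c(list(k = as.integer(k), seed = as.integer(seed)), best),
            class = "damscreen_gmm")
}

#' Posterior component responsibilities
#'
#' @param model A [fit_gmm()] model.
#' @param x Points (matrix, same dimension as the training data).
#' @return n x k matrix of posterior probabilities (rows sum to 1).
#' @export
gmm_posterior <- function(model, x) {
  x <- as.matrix(x)
  la <- .gmm_log_dens(x, model$means, model$covariances)
  la <- la + rep(log(model$weights), each = nrow(x))
  exp(la - .log_sum_exp_rows(la))
}

#' Hard cluster labels by maximum posterior
#' @inheritParams gmm_posterior
#' @return Integer labels in 1..k.
#' @export
gmm_labels <- function(model, x) {
  max.col(gmm_posterior(model, x), ties.method = "first")
}

#' Mean silhouette coefficient (Euclidean)
#'
#' For each point, `a` is its mean distance to the other members of its
#' own cluster and `b` the smallest mean distance to another cluster;
#' the silhouette is `(b - a) / max(a, b)`. Points in singleton clusters
#' contribute 0. Requires at least two clusters.
#'
#' @param points Numeric matrix of points.
#' @param labels Integer/character cluster labels, one per point.
#' @return Mean silhouette, in `[-1, 1]`. Per-point widths in attribute
#'   `"widths"`.
#' @export
silhouette_mean <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  n <- nrow(points)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L) {
    stop("silhouette needs at least two clusters", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(points))
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    nown <- sum(labels == own)
    if (nown == 1L) { s[i] <- 0; next }
    a <- sum(dm[i, labels == own]) / (nown - 1L)
    b <- min(vapply(ks[ks != own],
                    function(kk) mean(dm[i, labels == kk]), numeric(1L)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  structure(mean(s), widths = s)
}

#' Select the mixture component count by silhouette
#'
#' Fits a Gaussian mixture for every candidate k, labels points by
#' maximum posterior, and keeps the k whose mean silhouette coefficient is
#' closest to one (i.e. the maximum, since silhouettes never exceed 1).
#' Candidates with too few points, or whose labeling collapses to a single
#' cluster, are skipped with a warning.
#'
#' @param points Numeric matrix (n x 2 for the screen).
#' @param k_candidates Integer vector of component counts (default 3:5).
#' @param seed Base seed (each candidate uses `seed + k`).
#' @param ... Passed to [fit_gmm()].
#' @return List of class `damscreen_clustering`: `chosen_k`,
#'   `assignments` (labels under the chosen model), `mean_silhouette`
#'   (named per candidate), `models` (named per candidate), `points`.
#' @export
select_k <- function(points, k_candidates = 3:5, seed = 1L, ...) {
  points <- as.matrix(points)
  sil <- setNames(rep(NA_real_, length(k_candidates)), k_candidates)
  models <- setNames(vector("list", length(k_candidates)), k_candidates)
  labels <- setNames(vector("list", length(k_candidates)), k_candidates)
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    if (nrow(points) <= k) {
      warning("skipping k = ", k, ": not enough points", call. = FALSE)
      next
    }
    m <- fit_gmm(points, k, seed = seed + k, ...)
    lab <- gmm_labels(m, points)
    models[[i]] <- m
    labels[[i]] <- lab
    if (length(unique(lab)) < 2L) {
      warning("skipping k = ", k, ": labels collapsed to one cluster",
              call. = FALSE)
      next
    }
    sil[i] <- silhouette_mean(points, lab)
  }
  if (all(is.na(sil))) stop("no candidate k could be evaluated", call. = FALSE)
  best <- which.max(sil) # ties: first (smallest k)
  structure(list(
    chosen_k = k_candidates[best],
    assignments = labels[[best]],
    mean_silhouette = sil,
    models = models,
    points = points
  ), class = "damscreen_clustering")
}

#' Covariance ellipse of one mixture component
#'
#' The cluster ellipse drawn at `n_sigma` standard deviations: semi-axes
#' are `n_sigma * sqrt(eigenvalues)` of the component covariance, the
#' angle comes from the leading eigenvector.
#'
#' @param model A [fit_gmm()] model (2-D).
#' @param component Component index, 1..k.
#' @param n_sigma Radius in standard deviations.
#' @return List: `center` (length 2), `axes` (semi-axes, decreasing),
#'   `angle` (radians, leading axis vs x-axis).
#' @export
cluster_ellipse <- function(model, component, n_sigma = 1) {
  stopifnot(component >= 1L, component <= model$k)
  S <- model$covariances[, , component]
  e <- eigen(S, symmetric = TRUE)
  list(center = model$means[component, ],
       axes = n_sigma * sqrt(pmax(e$values, 0)),
       angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]))
}
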