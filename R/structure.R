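#' Principal component analysis of an encoded panel
#'
#' Column-centred (unscaled) PCA of the presence/absence matrix — the
#' covariance convention of \code{prcomp}'s default. The sign of each
#' component is fixed by making its largest-magnitude loading positive, so
#' results are deterministic across platforms.
#'
#' @param encoded an imputed \code{encoded_matrix} (no missing values); see
#'   \code{\link{impute_mean}}.
#' @param n_components number of components to keep; truncated to the
#'   matrix rank with a warning if larger.
#' @return object of class \code{panel_pca}: \code{scores}
#'   (n_samples x n_components), \code{explained_fraction} (per kept
#'   component, fractions of total variance), \code{loadings},
#'   \code{total_explained} (sum over kept components).
#' @export
panel_pca <- function(encoded, n_components = 5L) {
  v <- encoded$values
  if (anyNA(v)) stop("encoded matrix has missing values; run impute_mean first")
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  rank <- sum(var_all > max(var_all) * 1e-12)
  if (n_components > rank) {
    warning("n_components = ", n_components, " exceeds rank ", rank,
            "; truncated")
    n_components <- rank
  }
  keep <- seq_len(n_components)
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in keep) {
    piv <- which.max(abs(loadings[, j]))
    if (loadings[piv, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores,
                 explained_fraction = var_all[keep] / sum(var_all),
                 loadings = loadings,
                 total_explained = sum(var_all[keep]) / sum(var_all)),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat("panel_pca: ", nrow(x$scores), " samples, ", ncol(x$scores),
      " components\n", sep = "")
  cat("  explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = " "),
      " (total ", sprintf("%.1f%%", 100 * x$total_explained), ")\n", sep = "")
  invisible(x)
}

# log density of rows of x under one Gaussian component
gmm_log_dens <- function(x, mean, cov, model) {
  d <- ncol(x)
  xc <- sweep(x, 2L, mean)
  if (model == "spherical") {
    -0.5 * (d * log(2 * pi * cov) + rowSums(xc^2) / cov)
  } else if (model == "diagonal") {
    -0.5 * (d * log(2 * pi) + sum(log(cov)) +
              rowSums(sweep(xc^2, 2L, cov, "/")))
  } else {
    ch <- chol(cov)
    z <- xc %*% backsolve(ch, diag(d), transpose = FALSE) # x (R^-1)
    -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + rowSums(z^2))
  }
}

#' Gaussian-mixture clustering with BIC model selection
#'
#' Fits Gaussian mixtures by EM for every combination of component count K
#' and covariance model (spherical, diagonal, full), each initialized from
#' a k-means partition under a fixed seed, and returns the fit maximizing
#' BIC = 2 loglik - m log(n) (the orientation used by mclust, m = free
#' parameter count), with hard labels by maximum posterior.
#'
#' Singular covariances are ridge-regularized on the diagonal; if EM has
#' not converged after \code{max_iter} iterations the best iterate so far
#' is returned with a warning. The per-iteration log-likelihood trace is
#' kept (it is non-decreasing, a property of EM that the test suite
#' checks).
#'
#' @param scores numeric matrix (n_samples x n_dims), typically the first
#'   few PC scores.
#' @param K_range integer vector of component counts to try.
#' @param covariance_models subset of c("spherical", "diagonal", "full").
#' @param seed seed for the k-means initializations.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return object of class \code{gmm_model}: K, covariance_model, weights,
#'   means (K x d), covariances, loglik, loglik_trace, bic, assignments,
#'   and \code{candidates} (data.frame of all (K, model, bic) tried).
#' @export
fit_gmm_bic <- function(scores, K_range = 1:8,
                        covariance_models = c("spherical", "diagonal", "full"),
                        seed = 1L, max_iter = 500L, tol = 1e-8) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  d <- ncol(scores)
  if (n <= max(K_range)) stop("need n_samples > max(K_range)")
  covariance_models <- match.arg(covariance_models,
                                 c("spherical", "diagonal", "full"),
                                 several.ok = TRUE)
  best <- NULL
  cand <- list()
  for (model in covariance_models) {
    for (K in sort(K_range)) {
      set.seed(seed + K)
      fit <- gmm_em(scores, K, model, max_iter, tol)
      m_free <- (K - 1) + K * d +
        switch(model, spherical = K, diagonal = K * d, full = K * d * (d + 1) / 2)
      fit$bic <- 2 * fit$loglik - m_free * log(n)
      fit$K <- K
      fit$covariance_model <- model
      cand[[length(cand) + 1L]] <- data.frame(K = K, model = model,
                                              loglik = fit$loglik,
                                              bic = fit$bic)
    if (is.null(best) || fit$bic > best$bic) best <- fit
    }
  }
  best$candidates <- do.call(rbind, cand)
  class(best) <- "gmm_model"
  best
}

# EM for one (K, model); k-means initialization, ridge regularization
gmm_em <- function(x, K, model, max_iter, tol) {
  n <- nrow(x)
  d <- ncol(x)
  ridge <- 1e-6 * mean(apply(x, 2L, stats::var)) + 1e-10
  if (K == 1L) {
    z <- matrix(1, n, 1L)
  } else {
    km <- stats::kmeans(x, centers = K, nstart = 10L, iter.max = 50L)
    z <- outer(km$cluster, seq_len(K), "==") * 1
  }
  w <- colMeans(z)
  params <- gmm_mstep(x, z, model, ridge)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lp <- vapply(seq_len(K), function(k) {
      log(params$w[k]) + gmm_log_dens(x, params$mean[k, ], params$cov[[k]], model)
    }, numeric(n))
    lp <- matrix(lp, n, K)
    mx <- apply(lp, 1L, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) <= tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    prev <- ll
    z <- exp(lp - lse)
    params <- gmm_mstep(x, z, model, ridge)
  }
  if (!converged && max_iter > 1L)
    warning("EM did not converge in ", max_iter, " iterations; ",
            "returning best iterate")
  list(weights = params$w, means = params$mean, covariances = params$cov,
       loglik = trace[length(trace)], loglik_trace = trace,
       assignments = max.col(lp), posterior = exp(lp - lse))
}

gmm_mstep <- function(x, z, model, ridge) {
  n <- nrow(x)
  d <- ncol(x)
  K <- ncol(z)
  nk <- pmax(colSums(z), 1e-10)
  w <- nk / n
  mean_k <- t(vapply(seq_len(K), function(k) colSums(z[, k] * x) / nk[k],
                     numeric(d)))
  cov_k <- lapply(seq_len(K), function(k) {
    xc <- sweep(x, 2L, mean_k[k, ])
    if (model == "spherical") {
      max(sum(z[, k] * rowSums(xc^2)) / (nk[k] * d), ridge)
    } else if (model == "diagonal") {
      pmax(colSums(z[, k] * xc^2) / nk[k], ridge)
    } else {
      s <- crossprod(xc * sqrt(z[, k])) / nk[k]
      ok <- tryCatch({ chol(s); TRUE }, error = function(e) FALSE)
      if (!ok) s <- s + diag(ridge, d)
      s
    }
  })
  list(w = w, mean = mean_k, cov = cov_k)
}

#' @export
print.gmm_model <- function(x, ...) {
  cat("gmm_model: K = ", x$K, ", covariance = ", x$covariance_model,
      ", BIC = ", sprintf("%.1f", x$bic), "\n", sep = "")
  cat("  mixing weights: ", paste(sprintf("%.3f", x$weights), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Nei (1972) standard genetic distance between two populations
#'
#' D = -ln( J_XY / sqrt(J_X J_Y) ) with J_XY = sum over loci and alleles of
#' x y, J_X = sum of x^2, J_Y = sum of y^2, the sums taken across loci
#' before the ratio (the GenAlex convention). Loci lacking a defined
#' frequency in either population are dropped. D >= 0, D(X, X) = 0,
#' symmetric; complete divergence at every locus gives J_XY = 0 and D =
#' +Inf.
#'
#' @param freqs a \code{freq_table} from \code{\link{allele_freqs}}.
#' @param popA,popB group labels present in \code{freqs}.
#' @return non-negative numeric (possibly \code{Inf}).
#' @export
nei_distance <- function(freqs, popA, popB) {
  stopifnot(inherits(freqs, "freq_table"))
  if (!(popA %in% freqs$groups) || !(popB %in% freqs$groups))
    stop("unknown population label")
  x <- freqs$freq_a[popA, ]
  y <- freqs$freq_a[popB, ]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no locus with defined frequencies in both populations")
  x <- x[ok]
  y <- y[ok]
  j_xy <- sum(x * y + (1 - x) * (1 - y))
  j_x <- sum(x^2 + (1 - x)^2)
  j_y <- sum(y^2 + (1 - y)^2)
  if (j_xy == 0) {
    message("nei_distance: J_XY = 0 (complete divergence); returning Inf")
    return(Inf)
  }
  max(-log(j_xy / sqrt(j_x * j_y)), 0)
}

#' Pairwise Nei distance matrix over all groups of a frequency table
#'
#' @param freqs a \code{freq_table}.
#' @return symmetric matrix with zero diagonal, dimnames = group labels.
#' @export
nei_distance_matrix <- function(freqs) {
  g <- freqs$groups
  D <- matrix(0, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- nei_distance(freqs, g[i], g[j])
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \code{ape::nj}) over a symmetric
#' zero-diagonal distance matrix. For an additive input matrix the
#' topology and branch lengths are recovered exactly. Negative branch
#'-length estimates (possible for non-additive input) are clamped to zero
#' with the deficit transferred to an adjacent edge at the same node, so
#' path lengths between the affected neighbours are preserved and the
#' emitted Newick stays interpretable.
#'
#' @param D symmetric numeric matrix with zero diagonal and >= 3 labelled
#'   rows/columns.
#' @return an unrooted \code{ape} \code{phylo} tree with non-negative
#'   branch lengths.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need >= 3 labels")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (any(!is.finite(D))) stop("distances must be finite for tree building")
  tree <- ape::nj(stats::as.dist(D))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    node <- tree$edge[e, 1L]
    sib <- setdiff(which(tree$edge[, 1L] == node | tree$edge[, 2L] == node), e)
    if (length(sib)) {
      tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree
}
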