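#' Expected r-squared under drift-recombination equilibrium
#'
#' The decay curves fitted by \code{\link{ld_decay_fit}}, as functions of
#' physical distance d (bp) with C = 4 a d:
#' \itemize{
#'   \item \code{sved}: E(r2) = 1 / (1 + C), the large-sample
#'     drift-recombination equilibrium expectation; E(r2) = 1 at d = 0.
#'   \item \code{hill_weir_n}: the low-mutation, finite-sample (n
#'     gametes) adjustment
#'     E(r2) = ((10 + C) / ((2 + C)(11 + C))) *
#'             (1 + ((3 + C)(12 + 12 C + C^2)) / (n (2 + C)(11 + C))),
#'     which approaches the sved curve for large C and n.
#' }
#'
#' @param d physical distance in bp (vectorized).
#' @param a per-bp decay coefficient (> 0).
#' @param variant \code{"sved"} or \code{"hill_weir_n"}.
#' @param n sample size (gamete count), required for
#'   \code{"hill_weir_n"}.
#' @return expected r-squared.
#' @export
decay_curve <- function(d, a, variant = c("sved", "hill_weir_n"), n = NULL) {
  variant <- match.arg(variant)
  C <- 4 * a * d
  if (variant == "sved") {
    1 / (1 + C)
  } else {
    if (is.null(n)) stop("variant 'hill_weir_n' needs the sample size n")
    ((10 + C) / ((2 + C) * (11 + C))) *
      (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
  }
}

#' Fit an LD-decay model to r-squared versus physical distance
#'
#' Nonlinear least squares of observed pairwise r-squared on physical
#' distance under a drift-recombination-equilibrium expectation (see
#' \code{\link{decay_curve}}). Pairs enter the fit unbinned, one residual
#' per pair; \code{\link{bin_ld_pairs}} provides geometric-bin means for
#' plotting only. The single free parameter is the per-bp coefficient
#' \code{a} in C = 4 a d; it is initialized from the sved closed form
#' through the median observation and optimized by Levenberg-Marquardt
#' (\code{minpack.lm::nlsLM}) with a golden-section fallback, to relative
#' tolerance 1e-10. The decay distance at a target r-squared t is solved
#' on the fitted curve (closed form d = (1/t - 1) / (4 a) for sved,
#' numerically for hill_weir_n).
#'
#' @param pairs data.frame with columns \code{d} and \code{r2}, e.g. from
#'   \code{\link{compute_ld}} or \code{\link{pool_ld_pairs}}.
#' @param variant \code{"sved"} (default) or \code{"hill_weir_n"}.
#' @param n sample size (gametes) for the finite-sample variant; defaults
#'   to \code{2 * median(pairs$n)} when that column exists.
#' @param r2_targets thresholds at which to report the decay distance
#'   (default 0.2).
#' @return an object of class \code{ld_decay} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals} and \code{plot}. Fields: \code{variant}, \code{a},
#'   \code{n}, \code{rss}, \code{d_at} (named by threshold), \code{data}.
#' @examples
#' d <- 10^runif(500, 2, 6)
#' r2 <- decay_curve(d, a = 1e-5) + rnorm(500, sd = 0.03)
#' fit <- ld_decay_fit(data.frame(d = d, r2 = r2))
#' coef(fit)
#' fit$d_at
#' @export
ld_decay_fit <- function(pairs, variant = c("sved", "hill_weir_n"), n = NULL,
                         r2_targets = 0.2) {
  variant <- match.arg(variant)
  d <- as.numeric(pairs$d)
  r2 <- as.numeric(pairs$r2)
  ok <- is.finite(d) & is.finite(r2) & d >= 0
  d <- d[ok]
  r2 <- r2[ok]
  if (length(d) < 2L) stop("need at least 2 (d, r2) observations")
  d_pos <- d[d > 0]
  if (length(d) < 10L || length(d_pos) < 2L ||
      diff(range(log10(d_pos))) < 2)
    warning("fewer than 10 pairs or < 2 distance decades; fit may be weak")
  if (variant == "hill_weir_n" && is.null(n)) {
    if (!is.null(pairs$n)) n <- 2 * stats::median(pairs$n)
    else stop("variant 'hill_weir_n' needs the sample size n")
  }
  # initial a: sved closed form through the median point
  r2_med <- min(max(stats::median(r2), 1e-3), 1 - 1e-6)
  d_med <- max(stats::median(d), 1)
  a0 <- max((1 / r2_med - 1) / (4 * d_med), 1e-12)
  fn <- function(a) decay_curve(d, a, variant, n)
  a_hat <- tryCatch({
    df <- data.frame(d = d, r2 = r2)
    fit <- minpack.lm::nlsLM(
      r2 ~ decay_curve(d, a, variant, n), data = df,
      start = list(a = a0), lower = c(a = 1e-14),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 500))
    stats::coef(fit)[["a"]]
  }, error = function(e) {
    opt <- stats::optim(log(a0), function(la) sum((r2 - fn(exp(la)))^2),
                        method = "Brent", lower = log(1e-14), upper = log(10),
                        control = list(reltol = 1e-12))
    if (opt$convergence != 0)
      stop("decay fit did not converge (best a = ",
           signif(exp(opt$par), 6), ")")
    exp(opt$par)
  })
  if (!is.finite(a_hat) || a_hat <= 0)
    stop("decay fit rejected: a <= 0 at optimum")
  a_hat <- polish_gauss_newton(a_hat, d, r2, variant, n)
  rss <- sum((r2 - fn(a_hat))^2)
  d_at <- vapply(r2_targets, function(t) decay_d_at(a_hat, t, variant, n),
                 numeric(1))
  names(d_at) <- as.character(r2_targets)
  structure(list(variant = variant, a = a_hat, n = n, rss = rss,
                 d_at = d_at, data = data.frame(d = d, r2 = r2),
                 call = match.call()),
            class = "ld_decay")
}

# damped Gauss-Newton refinement of the 1-D least-squares problem, to
# relative tolerance 1e-12 on a (analytic derivative for sved, central
# finite difference otherwise)
polish_gauss_newton <- function(a, d, r2, variant, n, max_iter = 50L) {
  rss_at <- function(aa) sum((r2 - decay_curve(d, aa, variant, n))^2)
  rss <- rss_at(a)
  for (it in seq_len(max_iter)) {
    e <- decay_curve(d, a, variant, n)
    jac <- if (variant == "sved") {
      -4 * d / (1 + 4 * a * d)^2
    } else {
      h <- a * 1e-6
      (decay_curve(d, a + h, variant, n) -
         decay_curve(d, a - h, variant, n)) / (2 * h)
    }
    g <- sum(jac * (r2 - e))
    hess <- sum(jac^2)
    if (hess <= 0) break
    step <- g / hess
    while (a + step <= 0) step <- step / 2
    new_rss <- rss_at(a + step)
    halvings <- 0L
    while (new_rss > rss && halvings < 30L) {
      step <- step / 2
      new_rss <- rss_at(a + step)
      halvings <- halvings + 1L
    }
    if (new_rss > rss) break
    a_new <- a + step
    done <- abs(step) <= 1e-12 * a
    a <- a_new
    rss <- new_rss
    if (done) break
  }
  a
}

decay_d_at <- function(a, target, variant, n = NULL) {
  if (variant == "sved") return((1 / target - 1) / (4 * a))
  e0 <- decay_curve(0, a, variant, n)
  if (target >= e0) {
    message("fitted curve starts below target r2 = ", target,
            " (E at d = 0 is ", signif(e0, 4), "); no crossing")
    return(NA_real_)
  }
  upper <- 10 / a
  stats::uniroot(function(dd) decay_curve(dd, a, variant, n) - target,
                 lower = 0, upper = upper, tol = 1e-6 / a)$root
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay fit (", x$variant, ")\n", sep = "")
  cat("  a = ", signif(x$a, 6), " per bp; ", nrow(x$data), " pairs; RSS = ",
      signif(x$rss, 6), "\n", sep = "")
  for (t in names(x$d_at))
    cat("  distance at r2 = ", t, ": ",
        ifelse(is.na(x$d_at[[t]]), "none",
               sprintf("%.1f Kbp", x$d_at[[t]] / 1e3)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ld_decay <- function(object, ...) {
  out <- list(variant = object$variant, a = object$a, n = object$n,
              n_pairs = nrow(object$data), rss = object$rss,
              sigma = sqrt(object$rss / max(nrow(object$data) - 1, 1)),
              d_at = object$d_at)
  class(out) <- "summary.ld_decay"
  out
}

#' @export
print.summary.ld_decay <- function(x, ...) {
  cat("LD decay model: ", x$variant,
      if (!is.null(x$n)) paste0(" (n = ", x$n, " gametes)"), "\n", sep = "")
  cat("  pairs: ", x$n_pairs, "; a = ", signif(x$a, 6),
      " per bp; residual sd = ", signif(x$sigma, 4), "\n", sep = "")
  for (t in names(x$d_at))
    cat("  d_at(r2 = ", t, ") = ", signif(x$d_at[[t]], 6), " bp\n", sep = "")
  invisible(x)
}

#' @export
coef.ld_decay <- function(object, ...) c(a = object$a)

#' @export
predict.ld_decay <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$d
  else if (is.data.frame(newdata)) newdata$d
  else as.numeric(newdata)
  decay_curve(d, object$a, object$variant, object$n)
}

#' @export
residuals.ld_decay <- function(object, ...) {
  object$data$r2 - predict.ld_decay(object)
}

#' Geometric-bin means of LD pairs (for plotting)
#'
#' @param pairs data.frame with \code{d} and \code{r2}.
#' @param n_bins number of geometric distance bins.
#' @return data.frame with bin midpoint \code{d}, mean \code{r2} and pair
#'   count \code{n_pairs} per non-empty bin.
#' @export
bin_ld_pairs <- function(pairs, n_bins = 25L) {
  d <- pairs$d[pairs$d > 0]
  r2 <- pairs$r2[pairs$d > 0]
  br <- exp(seq(log(min(d)), log(max(d)), length.out = n_bins + 1L))
  br[1L] <- br[1L] * 0.999
  bin <- cut(d, br, labels = FALSE, include.lowest = TRUE)
  agg <- stats::aggregate(cbind(d = d, r2 = r2), by = list(bin = bin), mean)
  cnt <- as.integer(table(bin)[as.character(agg$bin)])
  data.frame(d = agg$d, r2 = agg$r2, n_pairs = cnt)
}

#' @export
plot.ld_decay <- function(x, n_bins = 25L, ...) {
  b <- bin_ld_pairs(x$data, n_bins)
  dd <- exp(seq(log(max(min(x$data$d[x$data$d > 0]), 1)),
                log(max(x$data$d)), length.out = 200))
  plot(b$d, b$r2, log = "x", xlab = "distance (bp)",
       ylab = expression(r^2), ylim = c(0, 1),
       main = paste0("LD decay (", x$variant, ")"), pch = 19, ...)
  graphics::lines(dd, decay_curve(dd, x$a, x$variant, x$n), col = "red3",
                  lwd = 2)
  for (t in as.numeric(names(x$d_at)))
    graphics::abline(h = t, lty = 3, col = "grey50")
  invisible(x)
}
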