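#' REML polygenic model fit
#'
#' Fits y = X b + u + e with var(u) = sigma2_g K, var(e) = sigma2_e I by
#' restricted maximum likelihood. The model is rotated into the
#' eigenbasis of K, so the profile REML likelihood is a cheap function of
#' the single parameter h2 = sigma2_g / (sigma2_g + sigma2_e); it is
#' maximised on a grid and refined by golden-section search to 1e-6.
#'
#' @param y numeric trait vector (missing rows dropped, with K and X
#'   aligned accordingly).
#' @param covariates design matrix of fixed effects (an intercept is added
#'   if absent); may be `NULL` for intercept-only.
#' @param K kinship matrix aligned with `y` (same order).
#' @param h2_fixed optionally skip optimisation and evaluate at this h2
#'   (used e.g. for oracle comparisons with known variance components).
#' @param grid_n grid resolution for the initial bracket.
#' @return object of class `polygenic_fit`: `sigma2_g`, `sigma2_e`, `h2`,
#'   `loglik` (restricted), `beta`, `se_beta`, `residuals` (y - X beta),
#'   `Vinv` (inverse fitted covariance), `ids`, `n`, `boundary`,
#'   `identifiable`, `loglik_grid`.
#' @export
fit_polygenic <- function(y, covariates = NULL, K, h2_fixed = NULL,
                          grid_n = 40) {
  ok <- !is.na(y)
  y <- y[ok]
  n <- length(y)
  if (n < 30) stop("degenerate input: need n >= 30", call. = FALSE)
  X <- if (is.null(covariates)) matrix(1, n, 1,
                                       dimnames = list(NULL, "(Intercept)"))
  else as.matrix(covariates)[ok, , drop = FALSE]
  if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0)))
    X <- cbind(`(Intercept)` = 1, X)
  if (qr(X)$rank < ncol(X))
    stop("identifiability error: covariates not full rank", call. = FALSE)
  K <- unclass(K)
  if (!all(dim(K) == c(length(ok), length(ok))))
    stop("format error: kinship not aligned with y", call. = FALSE)
  K <- K[ok, ok, drop = FALSE]
  p <- ncol(X)

  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)

  # restricted log-likelihood profiled over sigma2_p, as a function of h2
  rll <- function(h2) {
    w <- h2 * d + (1 - h2)
    if (any(w <= 0)) return(-Inf)
    XtW <- Xt / w
    XtWX <- crossprod(Xt, XtW)
    bhat <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - Xt %*% bhat
    rss <- sum(r^2 / w)
    s2 <- rss / (n - p)
    -0.5 * (sum(log(w)) + as.numeric(determinant(XtWX)$modulus) +
              (n - p) * log(s2))
  }

  grid <- seq(0, 0.999, length.out = grid_n)
  ll <- vapply(grid, rll, numeric(1))
  identifiable <- diff(range(ll[is.finite(ll)])) > 1e-8
  if (!identifiable)
    warning("variance components not identifiable (likelihood flat in h2); ",
            "is the kinship matrix (near) identity?")
  if (is.null(h2_fixed)) {
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE, tol = 1e-6)
    h2 <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  } else {
    stopifnot(h2_fixed >= 0, h2_fixed < 1)
    h2 <- h2_fixed
  }
  if (!is.finite(rll(h2)))
    stop("convergence error: restricted likelihood not finite at optimum; ",
         "grid trace: ", paste(signif(ll, 4), collapse = " "), call. = FALSE)

  w <- h2 * d + (1 - h2)
  XtW <- Xt / w
  XtWX <- crossprod(Xt, XtW)
  bhat <- drop(solve(XtWX, crossprod(XtW, yt)))
  r_rot <- drop(yt - Xt %*% bhat)
  s2p <- sum(r_rot^2 / w) / (n - p)
  Vinv <- eg$vectors %*% (t(eg$vectors) / (s2p * w))
  fit <- list(sigma2_g = h2 * s2p, sigma2_e = (1 - h2) * s2p, h2 = h2,
              loglik = rll(h2), beta = stats::setNames(bhat, colnames(X)),
              se_beta = sqrt(diag(solve(XtWX)) * s2p),
              residuals = drop(y - X %*% bhat), Vinv = Vinv,
              X = X, ok = ok, n = n,
              boundary = (is.null(h2_fixed) && (h2 < 1e-4 || h2 > 0.995)),
              identifiable = identifiable,
              loglik_grid = data.frame(h2 = grid, loglik = ll))
  class(fit) <- "polygenic_fit"
  fit
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf("polygenic fit: n = %d, h2 = %.3f (sigma2_g = %.4g, sigma2_e = %.4g)%s\n",
              x$n, x$h2, x$sigma2_g, x$sigma2_e,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
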