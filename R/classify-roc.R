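#' Composite Simpson integration on a uniform grid
#'
#' Requires an odd number of points (an even number of intervals); exact for
#' polynomials up to cubic.
#'
#' @param y ordinate values on a uniform grid
#' @param h grid spacing
#' @return the integral
#' @export
simpsonIntegrate <- function(y, h) {
  n <- length(y)
  stopifnot(n >= 3, n %% 2 == 1)
  w <- rep(c(4, 2), length.out = n - 2)
  h / 3 * (y[1] + y[n] + sum(w * y[2:(n - 1)]))
}

#' Fitted ROC curve and AUC from (FPR, TPR) points
#'
#' Fits the one-parameter concave family `TPR = FPR^(1/theta)`, `theta >= 1`
#' (constrained through (0,0) and (1,1) and monotone nondecreasing), to the
#' observed per-run operating points by least squares, then integrates the
#' fitted curve with Simpson's rule on a uniform FPR grid.
#'
#' @param points data.frame with columns `fpr`, `tpr`
#' @param nGrid number of grid points for the integration (odd)
#' @return list with `theta`, `auc`, and the fitted `curve` data.frame
#' @export
rocAuc <- function(points, nGrid = 101) {
  stopifnot(all(c("fpr", "tpr") %in% names(points)))
  pts <- points[is.finite(points$fpr) & is.finite(points$tpr), ]
  if (nrow(pts) == 0) stop("no finite ROC points")
  sse <- function(theta) sum((pts$tpr - pts$fpr^(1 / theta))^2)
  if (nrow(unique(pts)) == 1 && pts$fpr[1] == 0 && pts$tpr[1] == 1) {
    theta <- Inf
  } else {
    theta <- stats::optimize(sse, c(1, 500))$minimum
    if (sse(1) <= sse(theta)) theta <- 1
  }
  grid <- seq(0, 1, length.out = nGrid)
  fit <- if (is.infinite(theta)) c(0, rep(1, nGrid - 1)) else grid^(1 / theta)
  auc <- simpsonIntegrate(fit, grid[2] - grid[1])
  list(theta = theta, auc = min(max(auc, 0), 1),
       curve = data.frame(fpr = grid, tpr = fit))
}
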