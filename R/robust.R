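# Robust least squares with a soft-L1 loss.
#
# Minimizes sum_i s^2 * rho((r_i / s)^2) with rho(z) = 2 (sqrt(1 + z) - 1),
# which is quadratic for small residuals and linear for large ones. This is
# the loss used throughout for the error-decay and accuracy-scaling fits.
# Nelder-Mead exploration followed by a BFGS polish; on noiseless data the
# minimum coincides with the ordinary least-squares solution.

soft_l1_objective <- function(resid, scale = 1) {
  z <- (resid / scale)^2
  sum(scale^2 * 2 * (sqrt(1 + z) - 1))
}

#' @noRd
robust_ls <- function(predict_fn, start, x, y, scale = 1,
                      lower = NULL, upper = NULL) {
  obj <- function(par) {
    pred <- predict_fn(par, x)
    if (any(!is.finite(pred))) return(1e12)
    soft_l1_objective(y - pred, scale)
  }
  fit1 <- stats::optim(start, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
  fit2 <- tryCatch(
    stats::optim(fit1$par, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)),
    error = function(e) fit1
  )
  best <- if (fit2$value <= fit1$value) fit2 else fit1
  if (!is.finite(best$value)) {
    stop("robust least squares failed to converge; objective non-finite at ",
         paste(signif(best$par, 4), collapse = ", "))
  }
  pred <- predict_fn(best$par, x)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(par = best$par, objective = best$value, fitted = pred,
       residuals = y - pred, r2 = r2,
       convergence = best$convergence)
}

# Percentile bootstrap over (x, y) points for a robust_ls fit.
#' @noRd
robust_ls_bootstrap <- function(predict_fn, start, x, y, n_boot = 1000,
                                scale = 1, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  draws <- matrix(NA_real_, n_boot, length(start))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(
      robust_ls(predict_fn, start, x[idx], y[idx], scale = scale),
      error = function(e) NULL
    )
    if (!is.null(fit)) draws[b, ] <- fit$par
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- apply(draws, 2, stats::quantile, probs = probs, na.rm = TRUE)
  colnames(ci) <- names(start)
  list(ci = t(ci), draws = draws)
}
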