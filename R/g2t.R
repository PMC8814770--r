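#' Read high-resolution capsid records from TSV
#'
#' Reads a tab-separated table with header
#' `phage  t_value  lattice  genome_kbp` into a record data.frame as used
#' by [fit_g2t()]. The packaged 37-structure high-resolution table can be
#' loaded directly with [load_highres_fixture()].
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `phage_name`, `t_value`, `lattice`,
#'   `genome_kbp`, `source`.
#' @export
read_capsid_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  need <- c("phage", "t_value", "genome_kbp")
  if (!all(need %in% names(df))) {
    stop("records TSV must have columns: ", paste(need, collapse = ", "))
  }
  capsid_records(phage_name = df$phage,
                 t_value = as.numeric(df$t_value),
                 genome_kbp = as.numeric(df$genome_kbp),
                 lattice = if ("lattice" %in% names(df)) df$lattice else NA,
                 source = "high_resolution")
}

#' Construct capsid records
#'
#' @param phage_name Character phage names.
#' @param t_value Positive T-numbers.
#' @param genome_kbp Positive genome lengths in kilobase pairs.
#' @param lattice Optional lattice labels.
#' @param source `"high_resolution"` or `"predicted"`.
#' @return A data.frame of capsid records.
#' @export
capsid_records <- function(phage_name, t_value, genome_kbp,
                           lattice = NA, source = "high_resolution") {
  if (any(!is.finite(genome_kbp)) || any(genome_kbp <= 0)) {
    stop("genome_kbp must be positive")
  }
  if (any(!is.finite(t_value)) || any(t_value <= 0)) {
    stop("t_value must be positive")
  }
  data.frame(phage_name = as.character(phage_name),
             t_value = t_value,
             genome_kbp = genome_kbp,
             lattice = lattice,
             source = source,
             stringsAsFactors = FALSE)
}

# Fast closed-form OLS of y on x (single covariate), returning c(intercept,
# slope). Used inside resampling loops where lm() overhead dominates.
ols2 <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(my - slope * mx, slope)
}

#' Fit the allometric genome-to-T-number (G2T) model
#'
#' Fits the power law \eqn{T = b (G/G_0)^a} with \eqn{G_0 = 1} kbp by
#' ordinary least squares on the log-linearized form
#' \eqn{\ln T = a \ln(G/G_0) + \ln b} (natural logarithms). The exponent
#' `a` is the allometric exponent; the theoretical expectation for
#' quasi-spherical capsids packing DNA at constant density is 2/3 (see
#' [theoretical_exponent()]).
#'
#' @param records Capsid records as returned by [capsid_records()] or
#'   [load_highres_fixture()]; at least 3 rows, all values positive.
#' @param g0 Reference genome length (kbp) dividing G; default 1.
#' @return An object of class `g2t_fit`: a list with elements `a`, `ln_b`,
#'   `b`, `r2` (coefficient of determination in log-log space), `n`,
#'   `residuals_ln`, `g0`.
#' @examples
#' fit <- fit_g2t(load_highres_fixture())
#' fit$a   # ~0.71
#' @export
fit_g2t <- function(records, g0 = 1) {
  if (nrow(records) < 3) stop("need at least 3 records to fit")
  if (any(records$genome_kbp <= 0) || any(records$t_value <= 0)) {
    stop("genome_kbp and t_value must be strictly positive")
  }
  x <- log(records$genome_kbp / g0)
  y <- log(records$t_value)
  co <- ols2(x, y)
  fitted <- co[1] + co[2] * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(list(a = unname(co[2]), ln_b = unname(co[1]),
                 b = exp(unname(co[1])), r2 = r2, n = nrow(records),
                 residuals_ln = unname(y - fitted), g0 = g0),
            class = "g2t_fit")
}

#' @export
print.g2t_fit <- function(x, ...) {
  cat("G2T allometric fit: T =", signif(x$b, 3), "* (G/", x$g0, "kbp)^",
      signif(x$a, 3), "\n")
  cat("  n =", x$n, "; R^2 (ln-ln) =", round(x$r2, 4), "\n")
  invisible(x)
}

#' Predict a continuous T-number from genome length
#'
#' Direct back-transform \eqn{T = b (G/G_0)^a}; no smearing or
#' small-sample bias correction is applied.
#'
#' @param fit A `g2t_fit`.
#' @param genome_kbp Positive genome length(s) in kbp.
#' @return Numeric predicted T-number(s), continuous.
#' @export
predict_t <- function(fit, genome_kbp) {
  stopifnot(inherits(fit, "g2t_fit"))
  if (any(genome_kbp <= 0)) stop("genome_kbp must be positive")
  fit$b * (genome_kbp / fit$g0)^fit$a
}

#' Compare the power-law model with alternative functional forms
#'
#' Fits T as a function of G under five two-parameter functional forms --
#' power \eqn{b G^a}, exponential \eqn{b e^{aG}}, quadratic
#' \eqn{c_0 + c_1 G^2}, reciprocal \eqn{c_0 + c_1/G} and logarithmic
#' \eqn{c_0 + c_1 \ln G} -- each by least squares (log-linearized where the
#' form allows), and reports the coefficient of determination and mean
#' signed residual of each model computed on the raw T scale so that the
#' models are comparable.
#'
#' @inheritParams fit_g2t
#' @return A data.frame with columns `model`, `r2`, `residual_bias`, plus
#'   attribute `best` naming the model with maximal r2.
#' @export
compare_alternative_models <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 records")
  g <- records$genome_kbp
  t <- records$t_value
  if (length(unique(g)) < 2) stop("singular design: all genome lengths equal")
  r2_of <- function(pred) 1 - sum((t - pred)^2) / sum((t - mean(t))^2)
  preds <- list(
    power = {co <- ols2(log(g), log(t)); exp(co[1]) * g^co[2]},
    exponential = {co <- ols2(g, log(t)); exp(co[1] + co[2] * g)},
    quadratic = {co <- ols2(g^2, t); co[1] + co[2] * g^2},
    reciprocal = {co <- ols2(1 / g, t); co[1] + co[2] / g},
    logarithmic = {co <- ols2(log(g), t); co[1] + co[2] * log(g)}
  )
  out <- data.frame(
    model = names(preds),
    r2 = vapply(preds, r2_of, numeric(1)),
    residual_bias = vapply(preds, function(p) mean(t - p), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "best") <- out$model[which.max(out$r2)]
  out
}

#' Mean relative error of the G2T model versus training size
#'
#' For each training size `n`, repeatedly draws `n` records at random
#' without replacement, fits the model on them, predicts T for the
#' held-out records, and accumulates the absolute relative error
#' \eqn{|T_{pred} - T_{emp}| / T_{emp}}. Reports the mean and standard
#' deviation of the per-repetition mean relative error.
#'
#' @inheritParams fit_g2t
#' @param n_values Integer training sizes, each < `nrow(records)`.
#' @param reps Number of random splits per size.
#' @param seed Integer seed (required; the resampling is random).
#' @return A data.frame with columns `n`, `mean_relative_error`, `sd`.
#' @examples
#' \donttest{
#' mre_curve(load_highres_fixture(), 30, reps = 1000, seed = 1)
#' }
#' @export
mre_curve <- function(records, n_values, reps = 10000, seed) {
  if (missing(seed)) stop("seed is required for reproducibility")
  if (any(n_values >= nrow(records))) {
    stop("every n must be smaller than the number of records")
  }
  if (any(n_values < 2)) stop("n must be >= 2")
  if (reps < 1) stop("reps must be >= 1")
  set.seed(seed)
  lg <- log(records$genome_kbp)
  lt <- log(records$t_value)
  tv <- records$t_value
  g <- records$genome_kbp
  m <- nrow(records)
  out <- lapply(n_values, function(n) {
    rep_mre <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(m, n)
      co <- ols2(lg[idx], lt[idx])
      tp <- exp(co[1]) * g[-idx]^co[2]
      mean(abs(tp - tv[-idx]) / tv[-idx])
    }, numeric(1))
    c(mean(rep_mre), stats::sd(rep_mre))
  })
  out <- do.call(rbind, out)
  data.frame(n = n_values, mean_relative_error = out[, 1], sd = out[, 2])
}

#' Fit the exponential decay of the mean relative error
#'
#' Fits \eqn{MRE(n) = p e^{-qn} + w} to an [mre_curve()] table by robust
#' (soft-L1) least squares. `w` is the asymptotic error floor: the model
#' error that remains no matter how many high-resolution structures are
#' added. Confidence intervals come from a percentile bootstrap over the
#' (n, MRE) points.
#'
#' @param mre_table Data.frame with columns `n` and `mean_relative_error`
#'   (at least 4 rows).
#' @param n_boot Bootstrap resamples for the confidence intervals.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `error_decay_fit`: list with `p`, `q`, `w`,
#'   `r2`, `ci` (matrix of 95% intervals), and `predict(n)` via
#'   [predict_mre()].
#' @export
fit_error_decay <- function(mre_table, n_boot = 1000, seed = NULL) {
  if (nrow(mre_table) < 4) stop("need at least 4 (n, MRE) points")
  x <- mre_table$n
  y <- mre_table$mean_relative_error
  pred_fn <- function(par, x) par[1] * exp(-par[2] * x) + par[3]
  w0 <- min(y)
  p0 <- max(max(y) - w0, 1e-6)
  resid0 <- pmax(y - w0, 1e-3 * p0)
  q0 <- max(min(-ols2(x, log(resid0))[2], 10), 1e-3)
  start <- c(p = p0 * exp(q0 * min(x)), q = q0, w = w0)
  fit <- robust_ls(pred_fn, start, x, y)
  if (fit$convergence != 0) {
    warning("error-decay fit did not fully converge (optim code ",
            fit$convergence, "); inspect residuals")
  }
  boot <- robust_ls_bootstrap(pred_fn, fit$par, x, y, n_boot = n_boot,
                              seed = seed)
  structure(list(p = unname(fit$par["p"]), q = unname(fit$par["q"]),
                 w = unname(fit$par["w"]), r2 = fit$r2, ci = boot$ci,
                 fitted = fit$fitted, table = mre_table),
            class = "error_decay_fit")
}

#' Extrapolate the mean relative error to a training size
#'
#' @param decay An `error_decay_fit`.
#' @param n Training size(s), possibly beyond the fitted range.
#' @return Predicted MRE(n) = p e^(-q n) + w.
#' @export
predict_mre <- function(decay, n) {
  stopifnot(inherits(decay, "error_decay_fit"))
  decay$p * exp(-decay$q * n) + decay$w
}

#' Assign an icosahedral architecture (or "elongated") to a genome length
#'
#' Predicts a continuous T-number from the genome length, forms the
#' uncertainty interval \eqn{T \pm \Delta T} with
#' \eqn{\Delta T = T \cdot MRE}, and collects every enumerated
#' architecture whose T-value falls inside it. The selected architecture
#' is the candidate closest to the predicted T; remaining candidates are
#' kept as alternatives. When no valid icosahedral T-value lies within
#' the margin the capsid is categorized as `"elongated"`.
#'
#' @param fit A `g2t_fit`.
#' @param mre Mean relative error in (0, 1) setting the margin.
#' @param genome_kbp A single positive genome length (kbp).
#' @param architectures Architecture table from
#'   [enumerate_architectures()].
#' @return An object of class `architecture_assignment`: list with
#'   `genome_kbp`, `t_predicted`, `delta_t`, `candidates` (data.frame),
#'   `selected` (one-row data.frame, or the string `"elongated"`),
#'   `alternatives`, and `t_label` (formatted selected T or
#'   `"elongated"`).
#' @details Ties between equidistant candidates are broken in favour of
#'   the hexagonal lattice, then the smaller `t0`; hexagonal capsids are
#'   the majority among solved tailed-phage structures.
#' @export
assign_architecture <- function(fit, mre, genome_kbp,
                                architectures = enumerate_architectures()) {
  if (length(genome_kbp) != 1 || genome_kbp <= 0) {
    stop("genome_kbp must be a single positive length")
  }
  if (mre <= 0 || mre >= 1) stop("mre must be in (0, 1)")
  tp <- predict_t(fit, genome_kbp)
  delta <- tp * mre
  cand <- architectures[architectures$t_value >= tp - delta - 1e-12 &
                        architectures$t_value <= tp + delta + 1e-12, ,
                        drop = FALSE]
  if (nrow(cand) == 0) {
    selected <- "elongated"
    alternatives <- cand
    t_label <- "elongated"
  } else {
    d <- abs(cand$t_value - tp)
    ord <- order(d,
                 cand$lattice != "hexagonal",  # hexagonal first on ties
                 cand$t0)
    cand <- cand[ord, , drop = FALSE]
    selected <- cand[1, , drop = FALSE]
    alternatives <- cand[-1, , drop = FALSE]
    t_label <- format_t(selected$t_value)
  }
  structure(list(genome_kbp = genome_kbp, t_predicted = tp, delta_t = delta,
                 candidates = cand, selected = selected,
                 alternatives = alternatives, t_label = t_label),
            class = "architecture_assignment")
}

#' @export
print.architecture_assignment <- function(x, ...) {
  cat("Genome", x$genome_kbp, "kbp -> T_pred =", round(x$t_predicted, 2),
      "+/-", round(x$delta_t, 2), "->", x$t_label, "\n")
  invisible(x)
}

#' Genome-length range compatible with a T-number
#'
#' Inverts the assignment rule: the set of genome lengths G whose
#' prediction interval \eqn{T(G)(1 \pm mre)} contains `t_value`, i.e.
#' \deqn{G \in [ (t/(b(1+mre)))^{1/a}, (t/(b(1-mre)))^{1/a} ] G_0.}
#' Ranges of adjacent T-numbers may overlap.
#'
#' @inheritParams assign_architecture
#' @param t_value T-number (>= 1).
#' @return Numeric length-2 vector `c(lo, hi)` in kbp.
#' @export
t_to_genome_range <- function(fit, mre, t_value) {
  stopifnot(inherits(fit, "g2t_fit"))
  if (mre <= 0 || mre >= 1) stop("mre must be in (0, 1)")
  if (t_value < 1) stop("t_value must be >= 1")
  lo <- (t_value / (fit$b * (1 + mre)))^(1 / fit$a) * fit$g0
  hi <- (t_value / (fit$b * (1 - mre)))^(1 / fit$a) * fit$g0
  c(lo = lo, hi = hi)
}

#' Theoretical allometric exponent for quasi-spherical capsids
#'
#' For a quasi-spherical shell of radius R, the T-number is proportional
#' to the capsid surface (each capsid protein occupies a constant exterior
#' area, so \eqn{T \propto R^2}) while the genome is packed at constant
#' density in the interior volume (\eqn{G \propto R^3}). Eliminating R
#' gives \eqn{T \propto G^{2/3}}: the implied allometric exponent is the
#' ratio of the surface and volume scaling powers.
#'
#' @param surface_power Power of R in the T-number scaling (default 2).
#' @param volume_power Power of R in the genome scaling (default 3).
#' @return The implied exponent, `surface_power / volume_power` (2/3 by
#'   default).
#' @export
theoretical_exponent <- function(surface_power = 2, volume_power = 3) {
  surface_power / volume_power
}

#' Write / read a G2T fit as JSON
#'
#' The JSON stores `a`, `ln_b`, `r2`, `n`, `g0` and, when supplied, a
#' reference MRE (typically the extrapolated MRE at the record count).
#'
#' @param fit A `g2t_fit`.
#' @param path Output path.
#' @param mre_reference Optional reference mean relative error to embed.
#' @return `path`, invisibly (`write_g2t_fit`); a `g2t_fit`
#'   (`read_g2t_fit`).
#' @export
write_g2t_fit <- function(fit, path, mre_reference = NULL) {
  stopifnot(inherits(fit, "g2t_fit"))
  obj <- list(a = fit$a, ln_b = fit$ln_b, r2 = fit$r2, n = fit$n,
              g0 = fit$g0)
  if (!is.null(mre_reference)) obj$mre_reference <- mre_reference
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_g2t_fit
#' @export
read_g2t_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- structure(list(a = obj$a, ln_b = obj$ln_b, b = exp(obj$ln_b),
                        r2 = obj$r2, n = obj$n, residuals_ln = NULL,
                        g0 = obj$g0),
                   class = "g2t_fit")
  if (!is.null(obj$mre_reference)) attr(fit, "mre_reference") <- obj$mre_reference
  fit
}
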