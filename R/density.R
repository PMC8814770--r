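# Multimodal genome-length density estimation with region-specific
# cross-validated Gaussian kernel bandwidths.

# Gaussian KDE evaluated at `at` given sample `x` and bandwidth `bw`
# (bw is the kernel standard deviation).
gauss_kde <- function(at, x, bw) {
  vapply(at, function(p) mean(stats::dnorm(p, mean = x, sd = bw)),
         numeric(1))
}

#' Cross-validated Gaussian kernel bandwidth
#'
#' Grid-search bandwidth selection by k-fold cross-validation: for each
#' candidate bandwidth, the data are split into `folds` folds (seeded
#' shuffle) and the mean held-out log-likelihood under a Gaussian KDE of
#' the training fold is accumulated; the candidate with the highest mean
#' held-out log-likelihood wins.
#'
#' @param values Numeric sample (genome lengths, kbp); at least `folds`
#'   values.
#' @param candidate_bandwidths Positive candidate bandwidths. The default
#'   is 30 log-spaced values in [0.1, 30] kbp.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for the fold shuffle.
#' @return The selected bandwidth (kbp).
#' @export
select_bandwidth <- function(values,
                             candidate_bandwidths = default_bandwidth_grid(),
                             folds = 5, seed = 1) {
  values <- values[is.finite(values)]
  if (length(values) < folds) stop("need at least `folds` values in region")
  if (any(candidate_bandwidths <= 0)) stop("bandwidths must be positive")
  set.seed(seed)
  n <- length(values)
  fold_id <- sample(rep_len(seq_len(folds), n))
  score <- vapply(candidate_bandwidths, function(bw) {
    ll <- vapply(seq_len(folds), function(f) {
      train <- values[fold_id != f]
      test <- values[fold_id == f]
      if (length(train) == 0 || length(test) == 0) return(NA_real_)
      dens <- gauss_kde(test, train, bw)
      mean(log(pmax(dens, .Machine$double.xmin)))
    }, numeric(1))
    mean(ll, na.rm = TRUE)
  }, numeric(1))
  candidate_bandwidths[which.max(score)]
}

#' @rdname select_bandwidth
#' @export
default_bandwidth_grid <- function() exp(seq(log(0.1), log(30), length.out = 30))

#' Default genome-length regions
#'
#' The four genome-length groups used for region-specific bandwidth
#' selection: 17-130, 130-210, 210-270 and 270-498 kbp. Configurable
#' because the groups were identified visually.
#'
#' @return A data.frame with columns `lo`, `hi`.
#' @export
default_genome_regions <- function() {
  data.frame(lo = c(17, 130, 210, 270), hi = c(130, 210, 270, 498))
}

#' Multiregion kernel density estimate of genome lengths
#'
#' Splits the sample into disjoint genome-length regions, selects a
#' bandwidth per region by cross-validation ([select_bandwidth()]),
#' computes a Gaussian KDE per region on a common grid, weights each
#' region's density by its sample fraction, sums and renormalizes to unit
#' mass (trapezoid rule).
#'
#' @param values Genome lengths (kbp).
#' @param regions Data.frame with columns `lo`, `hi`; disjoint, ordered,
#'   covering the data range. Defaults to [default_genome_regions()].
#' @param candidate_bandwidths Candidate bandwidth grid.
#' @param folds CV folds for bandwidth selection.
#' @param grid_size Number of evaluation points (default 2048).
#' @param seed Seed for the CV shuffles.
#' @return An object of class `genome_density`: list with `grid`,
#'   `density`, `regions` (with selected `bandwidth`, `n`, `weight`), and
#'   `normalization` (the pre-normalization trapezoid mass).
#' @export
multiregion_density <- function(values, regions = default_genome_regions(),
                                candidate_bandwidths = default_bandwidth_grid(),
                                folds = 5, grid_size = 2048, seed = 1) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no values")
  lo <- regions$lo; hi <- regions$hi
  if (any(lo[-1] < hi[-length(hi)] - 1e-9)) stop("regions must be disjoint and ordered")
  # assign each value to a region (upper-edge inclusive on the last)
  reg_of <- rep(NA_integer_, length(values))
  for (i in seq_len(nrow(regions))) {
    inb <- values >= lo[i] & (values < hi[i] | (i == nrow(regions) & values <= hi[i]))
    reg_of[inb & is.na(reg_of)] <- i
  }
  if (any(is.na(reg_of))) {
    stop("values outside all regions: e.g. ",
         paste(utils::head(values[is.na(reg_of)], 3), collapse = ", "))
  }
  used <- sort(unique(reg_of))
  bws <- rep(NA_real_, nrow(regions))
  for (i in used) {
    v <- values[reg_of == i]
    bws[i] <- if (length(v) >= folds) {
      select_bandwidth(v, candidate_bandwidths, folds = folds,
                       seed = seed + i)
    } else {
      # too few points for CV: fall back to the smallest candidate
      min(candidate_bandwidths)
    }
  }
  max_bw <- max(bws, na.rm = TRUE)
  grid <- seq(min(values) - 3 * max_bw, max(values) + 3 * max_bw,
              length.out = grid_size)
  dens <- numeric(grid_size)
  weights <- numeric(nrow(regions))
  for (i in used) {
    v <- values[reg_of == i]
    weights[i] <- length(v) / length(values)
    dens <- dens + weights[i] * gauss_kde(grid, v, bws[i])
  }
  mass <- trapz(grid, dens)
  dens <- dens / mass
  structure(list(grid = grid, density = dens,
                 regions = data.frame(lo = lo, hi = hi, bandwidth = bws,
                                      n = tabulate(reg_of, nrow(regions)),
                                      weight = weights),
                 normalization = mass),
            class = "genome_density")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Topographic prominence of local maxima: height above the higher of the
# two lowest points separating the peak from higher terrain (or the signal
# edge).
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(i) {
    left <- y[seq_len(i - 1)]
    right <- if (i < length(y)) y[(i + 1):length(y)] else numeric(0)
    higher_l <- which(left > y[i])
    base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):(i - 1)]) else
      if (length(left)) min(left) else y[i]
    higher_r <- which(right > y[i])
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)]) else
      if (length(right)) min(right) else y[i]
    y[i] - max(base_l, base_r)
  }, numeric(1))
}

#' Locate peaks of a genome-length density
#'
#' Finds strict local maxima of the estimated density above a minimum
#' topographic prominence (default 1% of the maximum density, suppressing
#' numerical-noise maxima). When a G2T fit is supplied, each peak is
#' annotated with its architecture assignment.
#'
#' @param estimate A `genome_density` from [multiregion_density()], or any
#'   list with `grid` and `density`.
#' @param prominence_frac Minimum prominence as a fraction of the maximum
#'   density.
#' @param fit Optional `g2t_fit` for annotation.
#' @param mre Margin used in [assign_architecture()] when `fit` is given.
#' @param architectures Architecture table used for annotation.
#' @return A data.frame (class `peak_set`) with columns `genome_kbp`,
#'   `density`, and, when annotated, `t_label`, `t_predicted`,
#'   `alt_labels`. Zero rows when the density has no qualifying peak.
#' @export
find_density_peaks <- function(estimate, prominence_frac = 0.01,
                               fit = NULL, mre = 0.09,
                               architectures = enumerate_architectures()) {
  y <- estimate$density
  x <- estimate$grid
  if (length(y) < 3) stop("grid must have at least 3 points")
  i <- 2:(length(y) - 1)
  peaks <- i[y[i] > y[i - 1] & y[i] > y[i + 1]]
  if (length(peaks)) {
    prom <- peak_prominence(y, peaks)
    peaks <- peaks[prom >= prominence_frac * max(y)]
  }
  out <- data.frame(genome_kbp = x[peaks], density = y[peaks])
  if (!is.null(fit) && nrow(out)) {
    asg <- lapply(out$genome_kbp, function(g)
      assign_architecture(fit, mre, g, architectures))
    out$t_label <- vapply(asg, `[[`, character(1), "t_label")
    out$t_predicted <- vapply(asg, `[[`, numeric(1), "t_predicted")
    out$alt_labels <- vapply(asg, function(a) {
      alt <- a$alternatives
      if (is.data.frame(alt) && nrow(alt)) {
        paste(format_t(alt$t_value), collapse = ",")
      } else ""
    }, character(1))
  }
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Tally predicted architecture frequencies
#'
#' Counts architecture labels and reports percentages, with separate
#' icosahedral and elongated totals.
#'
#' @param assignments A list of `architecture_assignment` objects, or a
#'   character vector of T labels (e.g. `"7"`, `"9.33"`, `"elongated"`).
#' @return A data.frame with columns `t_label`, `count`, `percent`,
#'   ordered by decreasing count; attributes `icosahedral_percent` and
#'   `elongated_percent`.
#' @export
tally_architectures <- function(assignments) {
  labels <- if (is.character(assignments)) assignments
            else vapply(assignments, `[[`, character(1), "t_label")
  if (length(labels) == 0) stop("no assignments to tally")
  tab <- sort(table(labels), decreasing = TRUE)
  out <- data.frame(t_label = names(tab), count = as.integer(tab),
                    percent = 100 * as.integer(tab) / length(labels),
                    stringsAsFactors = FALSE)
  attr(out, "elongated_percent") <-
    100 * sum(labels == "elongated") / length(labels)
  attr(out, "icosahedral_percent") <-
    100 * sum(labels != "elongated") / length(labels)
  out
}
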