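# Seeded synthetic-data generators and the packaged high-resolution
# fixture. The generators define the conditions under which the pipeline
# is tested without external downloads: power-law (genome, T) records
# with multiplicative lognormal noise, multimodal genome-length
# mixtures, and MCP sequence classes separable by length and amino-acid
# composition.

#' Load the packaged high-resolution capsid table
#'
#' The 37 tailed-phage capsids with solved 3D structures, their
#' T-numbers (including the trihexagonal 9.33 architectures of P74-26
#' and P23-45) and genome lengths in kbp. Lattice labels are
#' `"unspecified"` for T-values realizable on both lattices.
#'
#' @return A capsid-record data.frame (37 rows).
#' @export
load_highres_fixture <- function() {
  path <- system.file("extdata", "highres_capsids.tsv",
                      package = "capsidarch", mustWork = TRUE)
  read_capsid_records(path)
}

#' Simulate power-law (genome, T) records
#'
#' Genome lengths are sampled log-uniformly on [15, 500] kbp (the
#' observed tailed-phage range) and T-numbers follow
#' \eqn{T = b G^a e^\varepsilon} with \eqn{\varepsilon \sim N(0,
#' \sigma^2)} (multiplicative lognormal noise). Defaults emulate the
#' empirical scaling: a = 0.67, b = 0.5, sigma = 0.1.
#'
#' @param n Number of records (>= 3).
#' @param a_true,b_true True allometric parameters.
#' @param noise_sd Lognormal noise sigma (>= 0).
#' @param seed Integer seed.
#' @param g_range Genome-length sampling range (kbp).
#' @return A capsid-record data.frame with `source = "predicted"`.
#' @export
simulate_g2t_records <- function(n = 200, a_true = 0.67, b_true = 0.5,
                                 noise_sd = 0.1, seed,
                                 g_range = c(15, 500)) {
  if (missing(seed)) stop("seed is required")
  if (n < 3) stop("n must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  g <- exp(stats::runif(n, log(g_range[1]), log(g_range[2])))
  t <- b_true * g^a_true * exp(stats::rnorm(n, 0, noise_sd))
  capsid_records(phage_name = sprintf("sim%04d", seq_len(n)),
                 t_value = t, genome_kbp = g, source = "predicted")
}

#' Simulate a multimodal genome-length mixture
#'
#' Draws genome lengths from a Gaussian mixture, truncated to positive
#' values.
#'
#' @param component_means,component_sds Mixture component parameters
#'   (kbp).
#' @param weights Mixture weights (must sum to 1).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Numeric genome lengths (kbp).
#' @export
simulate_genome_mixture <- function(component_means, component_sds,
                                    weights, n, seed) {
  if (missing(seed)) stop("seed is required")
  if (length(component_means) != length(component_sds) ||
      length(component_means) != length(weights)) {
    stop("mixture parameter lengths differ")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  x <- stats::rnorm(n, component_means[comp], component_sds[comp])
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), component_means[comp[bad]],
                           component_sds[comp[bad]])
  }
  x
}

#' Define an MCP sequence-class profile
#'
#' @param class_id Class identifier.
#' @param t_value The architecture T-number the class emulates.
#' @param length_mean,length_sd Sequence length distribution (residues).
#' @param aa_weights Named 20-vector of amino-acid sampling weights
#'   (must sum to 1).
#' @return A list of class `mcp_class_profile`.
#' @export
mcp_class_profile <- function(class_id, t_value, length_mean,
                              length_sd = 10, aa_weights = NULL) {
  if (is.null(aa_weights)) {
    aa_weights <- stats::setNames(rep(1 / 20, 20), CANONICAL_AA)
  }
  aa_weights <- aa_weights[CANONICAL_AA]
  if (any(is.na(aa_weights)) || any(aa_weights < 0) ||
      abs(sum(aa_weights) - 1) > 1e-9) {
    stop("aa_weights must be a valid simplex over the 20 canonical residues")
  }
  if (length_mean <= 0) stop("length_mean must be positive")
  structure(list(class_id = class_id, t_value = t_value,
                 length_mean = length_mean, length_sd = length_sd,
                 aa_weights = aa_weights),
            class = "mcp_class_profile")
}

#' Simulate labelled MCP sequence classes
#'
#' Draws sequences i.i.d. per residue from each profile's amino-acid
#' weights with lengths ~ round(Normal(mean, sd)) clipped at 30, and
#' back-computes a genome length from the class T-value through the
#' inverse G2T map with small lognormal jitter, so that library building
#' round-trips the labels.
#'
#' @param profiles List of [mcp_class_profile()]s (>= 2).
#' @param n_per_class Entries per class.
#' @param seed Integer seed.
#' @param fit `g2t_fit` used for the inverse map; defaults to the fit of
#'   the packaged high-resolution table.
#' @param genome_jitter_sd Lognormal jitter sigma on the back-computed
#'   genome length (default 0.02, small enough to keep the label's
#'   assignment interval).
#' @return A labelled MCP entry data.frame with `t_label`, `t_numeric`
#'   and `true_class` columns.
#' @export
simulate_mcp_classes <- function(profiles, n_per_class, seed,
                                 fit = NULL, genome_jitter_sd = 0.02) {
  if (missing(seed)) stop("seed is required")
  if (length(profiles) < 2) stop("need at least 2 profiles")
  if (is.null(fit)) fit <- fit_g2t(load_highres_fixture())
  set.seed(seed)
  out <- list()
  for (p in profiles) {
    lens <- pmax(30, round(stats::rnorm(n_per_class, p$length_mean,
                                        p$length_sd)))
    seqs <- vapply(lens, function(L) {
      paste(sample(CANONICAL_AA, L, replace = TRUE, prob = p$aa_weights),
            collapse = "")
    }, character(1))
    g <- (p$t_value / fit$b)^(1 / fit$a) * fit$g0 *
      exp(stats::rnorm(n_per_class, 0, genome_jitter_sd))
    out[[length(out) + 1]] <- data.frame(
      id = sprintf("%s_%03d", p$class_id, seq_len(n_per_class)),
      phage_name = sprintf("%s_phage_%03d", p$class_id,
                           seq_len(n_per_class)),
      genome_kbp = g, sequence = seqs,
      t_label = format_t(p$t_value), t_numeric = p$t_value,
      true_class = p$class_id, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
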