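fixture <- load_highres_fixture()
fit_hr <- fit_g2t(fixture)

test_that("exact power-law data is recovered to machine precision", {
  g <- c(8, 27, 64, 125, 216)
  recs <- capsid_records(paste0("p", 1:5), 2 * g^(2 / 3), g)
  fit <- fit_g2t(recs)
  expect_equal(fit$a, 2 / 3, tolerance = 1e-12)
  expect_equal(fit$b, 2, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("fitting validates its inputs and is deterministic", {
  expect_error(fit_g2t(fixture[1:2, ]), "at least 3")
  bad <- fixture; bad$genome_kbp[1] <- -1
  expect_error(capsid_records(bad$phage_name, bad$t_value, bad$genome_kbp))
  expect_identical(fit_g2t(fixture)$a, fit_g2t(fixture)$a)
})

test_that("simulate-and-refit recovers the exponent within tolerance", {
  recs <- simulate_g2t_records(200, a_true = 0.67, b_true = 0.5,
                               noise_sd = 0.1, seed = 11)
  fit <- fit_g2t(recs)
  expect_lt(abs(fit$a - 0.67), 0.03)

  # unbiasedness over replicates (Monte-Carlo oracle)
  a_hat <- vapply(1:200, function(s) {
    fit_g2t(simulate_g2t_records(200, 0.67, 0.5, 0.1, seed = 1000 + s))$a
  }, numeric(1))
  expect_lt(abs(mean(a_hat) - 0.67), 0.005)
})

test_that("alternative-model comparison ranks functional forms", {
  g <- exp(seq(log(16), log(500), length.out = 40))
  pow <- capsid_records(paste0("p", 1:40), 0.5 * g^0.7, g)
  cmp <- compare_alternative_models(pow)
  expect_equal(cmp$r2[cmp$model == "power"], 1, tolerance = 1e-9)
  expect_lt(cmp$r2[cmp$model == "logarithmic"], 1)
  expect_identical(attr(cmp, "best"), "power")

  quad <- capsid_records(paste0("q", 1:40), 2 + 3e-4 * g^2, g)
  cmpq <- compare_alternative_models(quad)
  expect_identical(attr(cmpq, "best"), "quadratic")

  same_g <- capsid_records(paste0("s", 1:5), c(4, 7, 7, 9, 12), rep(40, 5))
  expect_error(compare_alternative_models(same_g), "singular")
})

test_that("the power model is best on the high-resolution table", {
  cmp <- compare_alternative_models(fixture)
  expect_identical(attr(cmp, "best"), "power")
  expect_true(all(cmp$r2[cmp$model == "power"] >= cmp$r2))
})

test_that("predict_t is the direct back-transform", {
  fit <- structure(list(a = 2 / 3, ln_b = 0, b = 1, r2 = 1, n = 0,
                        residuals_ln = NULL, g0 = 1), class = "g2t_fit")
  expect_equal(predict_t(fit, 8), 4)
  expect_equal(predict_t(fit, 1), 1)
  expect_error(predict_t(fit, -2), "positive")
  # consistency with the HK97 row under the fitted model
  expect_lt(abs(predict_t(fit_hr, 39.7) - 7) / 7, 0.09)
})

test_that("the MRE curve is zero without noise and decays with n", {
  g <- exp(seq(log(16), log(500), length.out = 20))
  clean <- capsid_records(paste0("p", 1:20), 0.5 * g^0.7, g)
  m <- mre_curve(clean, c(3, 10), reps = 50, seed = 5)
  expect_equal(m$mean_relative_error, c(0, 0), tolerance = 1e-10)

  m_hr <- mre_curve(fixture, c(5, 30), reps = 2000, seed = 6)
  expect_gt(m_hr$mean_relative_error[1], m_hr$mean_relative_error[2])
  expect_error(mre_curve(fixture, 37, reps = 10, seed = 1), "smaller")
  expect_error(mre_curve(fixture, 10, reps = 10), "seed")
})

test_that("error-decay fit recovers noiseless parameters with sane CIs", {
  n <- 5:30
  y <- 0.5 * exp(-0.2 * n) + 0.05
  tab <- data.frame(n = n, mean_relative_error = y)
  fit <- fit_error_decay(tab, n_boot = 200, seed = 9)
  expect_equal(fit$p, 0.5, tolerance = 1e-3)
  expect_equal(fit$q, 0.2, tolerance = 1e-3)
  expect_equal(fit$w, 0.05, tolerance = 1e-4)
  expect_gt(fit$r2, 0.9999)
  # bootstrap intervals contain the point estimates
  expect_true(fit$ci["p", 1] <= fit$p && fit$p <= fit$ci["p", 2])
  expect_true(fit$ci["w", 1] <= fit$w && fit$w <= fit$ci["w", 2])
  # extrapolation approaches the asymptote
  expect_equal(predict_mre(fit, 1e6), 0.05, tolerance = 1e-6)
  expect_error(fit_error_decay(tab[1:3, ]), "at least 4")
})

test_that("architecture assignment selects nearest valid T or elongated", {
  fit1 <- structure(list(a = 1, ln_b = 0, b = 1, r2 = 1, n = 0,
                         residuals_ln = NULL, g0 = 1), class = "g2t_fit")
  arch <- enumerate_architectures(60)
  # T_pred = 7: 16/3 and 28/3 are outside [6.37, 7.63]
  a7 <- assign_architecture(fit1, 0.09, 7, arch)
  expect_equal(a7$t_label, "7")
  expect_equal(nrow(a7$candidates), 1L)
  # no valid T near 2
  a2 <- assign_architecture(fit1, 0.09, 2, arch)
  expect_identical(a2$selected, "elongated")
  # an exact valid T with a tiny margin selects itself
  a12 <- assign_architecture(fit1, 1e-6, 12, arch)
  expect_equal(a12$t_label, "12")
  # both lattices appear as candidates for T = 12 at a wider margin
  a12w <- assign_architecture(fit1, 0.05, 12, arch)
  expect_setequal(
    a12w$candidates$lattice[abs(a12w$candidates$t_value - 12) < 1e-9],
    c("hexagonal", "trihexagonal"))
  # tie at equal distance prefers the hexagonal lattice
  expect_identical(a12w$selected$lattice, "hexagonal")
})

test_that("t_to_genome_range inverts the assignment interval", {
  fit1 <- structure(list(a = 2 / 3, ln_b = 0, b = 1, r2 = 1, n = 0,
                         residuals_ln = NULL, g0 = 1), class = "g2t_fit")
  r <- t_to_genome_range(fit1, 0.09, 4)
  expect_equal(unname(r), c((4 / 1.09)^1.5, (4 / 0.91)^1.5),
               tolerance = 1e-12)
  expect_lt(r[1], r[2])
  expect_error(t_to_genome_range(fit1, 1.2, 4), "mre")
})

test_that("assignment and genome ranges are mutually consistent", {
  arch <- enumerate_architectures(60)
  set.seed(42)
  for (i in 1:60) {
    g <- exp(runif(1, log(16), log(500)))
    t <- sample(arch$t_value, 1)
    a <- assign_architecture(fit_hr, 0.09, g, arch)
    r <- t_to_genome_range(fit_hr, 0.09, t)
    in_range <- g >= r[1] && g <= r[2]
    in_cands <- any(abs(a$candidates$t_value - t) < 1e-9)
    expect_identical(in_range, in_cands)
  }
})

test_that("quasi-spherical scaling implies a 2/3 exponent", {
  expect_equal(theoretical_exponent(), 2 / 3)
  expect_equal(theoretical_exponent(2, 3), 2 / 3)
})

test_that("G2T fit JSON round-trips", {
  path <- tempfile(fileext = ".json")
  write_g2t_fit(fit_hr, path, mre_reference = 0.09)
  back <- read_g2t_fit(path)
  expect_equal(back$a, fit_hr$a)
  expect_equal(back$b, fit_hr$b)
  expect_equal(attr(back, "mre_reference"), 0.09)
})
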