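fit_hr <- fit_g2t(load_highres_fixture())
arch60 <- enumerate_architectures(60)

test_that("the 22-feature vector counts canonical residues only", {
  f <- compute_features("GGGG")
  expect_equal(unname(f["length"]), 4)
  expect_equal(unname(f["freq_G"]), 1)
  expect_equal(sum(f[paste0("freq_", AA20)]), 1)

  u <- compute_features("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(abs(u[paste0("freq_", AA20)] - 0.05) < 1e-12))

  expect_message(x <- compute_features("GGXGG"), "1 non-canonical")
  expect_equal(unname(x["length"]), 4)
  expect_equal(unname(x["freq_G"]), 1)
  expect_error(compute_features(""), "non-empty")
  expect_error(suppressMessages(compute_features("XXX")), "no canonical")
  expect_length(f, 22)
  expect_identical(names(f), feature_names())
})

test_that("isoelectric point has the right acid/base behaviour", {
  expect_lt(isoelectric_point("DDDDDEEEEE"), 7)
  expect_gt(isoelectric_point("KKKKKRRRRR"), 7)
  # pure function: same sequence, same value
  expect_identical(isoelectric_point("MKTAYIAKQR"),
                   isoelectric_point("MKTAYIAKQR"))
})

test_that("bisection pI agrees with an independent grid scan", {
  pka <- load_pka_table()
  # independent brute-force oracle with the same pKa table
  grid_pi <- function(seq) {
    aa <- strsplit(seq, "")[[1]]
    pos <- pka[pka$type == "pos", ]
    neg <- pka[pka$type == "neg", ]
    ph <- seq(0, 14, by = 1e-5)
    q <- rep(0, length(ph))
    for (r in seq_len(nrow(pos))) {
      n <- if (pos$group[r] == "Nterm") 1 else sum(aa == pos$group[r])
      q <- q + n / (1 + 10^(ph - pos$pka[r]))
    }
    for (r in seq_len(nrow(neg))) {
      n <- if (neg$group[r] == "Cterm") 1 else sum(aa == neg$group[r])
      q <- q - n / (1 + 10^(neg$pka[r] - ph))
    }
    ph[which.min(abs(q))]
  }
  for (s in c("ACDEFGHIKLMNPQRSTVWY", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")) {
    expect_equal(isoelectric_point(s, pka), grid_pi(s), tolerance = 1e-3)
  }
})

test_that("the class scheme merges overlapping ranges and groups jumbos", {
  scheme <- build_class_scheme(arch60, fit_hr, 0.09)
  ids <- vapply(scheme$classes, `[[`, character(1), "class_id")
  # T = 9 and 9.33: ratio 1.037 < (1.09/0.91), ranges overlap -> merged
  expect_identical(t_label_to_class(scheme, "9"),
                   t_label_to_class(scheme, "9.33"))
  # T = 4 and 7 are separated under a 9% margin
  expect_false(t_label_to_class(scheme, "4") ==
                 t_label_to_class(scheme, "7"))
  # all large T collapse into the jumbo class
  for (lb in c("25.33", "27", "28", "31", "52")) {
    expect_identical(t_label_to_class(scheme, lb), scheme$jumbo_class)
  }
  expect_identical(t_label_to_class(scheme, "elongated"),
                   scheme$elongated_class)
  expect_true(scheme$jumbo_class %in% ids)
  # genome ranges of distinct non-jumbo classes do not overlap
  small <- Filter(function(cl) length(cl$member_t_values) &&
                    all(cl$member_t_values < 25), scheme$classes)
  rng <- t(vapply(small, `[[`, numeric(2), "genome_range"))
  rng <- rng[order(rng[, 1]), ]
  expect_true(all(rng[-1, 1] >= rng[-nrow(rng), 2] - 1e-9))
})

test_that("training is seeded-deterministic and fits separable classes", {
  lib <- simulate_mcp_classes(separable_profiles(), 30, seed = 21)
  feats <- featurize_library(lib)
  m1 <- train_classifier(feats, lib$true_class, seed = 5)
  m2 <- train_classifier(feats, lib$true_class, seed = 5)
  p1 <- predict(m1, feats)
  p2 <- predict(m2, feats)
  expect_identical(p1$predicted_class, p2$predicted_class)
  expect_identical(p1$class_probability, p2$class_probability)
  expect_equal(mean(p1$predicted_class == lib$true_class), 1)
  expect_error(train_classifier(feats, rep("one", nrow(feats))),
               "2 classes")
})

test_that("label-permuted training yields chance-level accuracy", {
  lib <- simulate_mcp_classes(separable_profiles(), 60, seed = 22)
  feats <- featurize_library(lib)
  set.seed(23)
  shuffled <- sample(lib$true_class)
  tr <- sample.int(nrow(lib), 60)
  m <- train_classifier(feats[tr, ], shuffled[tr], seed = 24)
  p <- predict(m, feats[-tr, ])
  acc <- mean(p$predicted_class == shuffled[-tr])
  expect_lt(abs(acc - 0.5), 0.25)  # 2 classes: chance = 0.5
})

test_that("split evaluation applies the correctness margin", {
  lib <- simulate_mcp_classes(separable_profiles(), 30, seed = 25)
  scheme <- build_class_scheme(arch60, fit_hr, 0.09)
  feats <- featurize_library(lib)
  ev <- evaluate_classifier(lib, scheme, n_splits = 8, seed = 26,
                            features = feats)
  expect_gt(ev$overall_accuracy, 0.95)
  expect_equal(dim(ev$confusion_mean), c(2, 2))
  expect_equal(unname(rowSums(ev$morphology_mean)["icosahedral"]), 1)

  # a singleton class in the test set is counted incorrect, not fatal:
  # correctness of a prediction against a label of a class never trained
  ok <- capsidarch:::class_correct(scheme, rep("7", 2), c("19", "7"))
  expect_identical(ok, c(FALSE, TRUE))
  # jumbo margin: any member T >= 25 within 9% counts
  expect_true(capsidarch:::class_correct(scheme, scheme$jumbo_class, "27"))
  expect_false(capsidarch:::class_correct(scheme, scheme$jumbo_class,
                                          "elongated"))
})

test_that("seeded evaluation is reproducible bit-for-bit", {
  lib <- simulate_mcp_classes(separable_profiles(), 20, seed = 27)
  scheme <- build_class_scheme(arch60, fit_hr, 0.09)
  feats <- featurize_library(lib)
  e1 <- evaluate_classifier(lib, scheme, n_splits = 3, seed = 28,
                            features = feats)
  e2 <- evaluate_classifier(lib, scheme, n_splits = 3, seed = 28,
                            features = feats)
  expect_identical(e1$overall_accuracy, e2$overall_accuracy)
  expect_identical(e1$confusion_mean, e2$confusion_mean)
})

test_that("accuracy grows log-linearly and the scaling fit inverts", {
  # noiseless refit: exact recovery and exact inversion
  tab <- data.frame(n = c(50, 100, 200, 400, 800),
                    mean_accuracy = 0.2 * log10(c(50, 100, 200, 400, 800)) +
                      0.3)
  fit <- fit_log_accuracy(tab, n_boot = 50, seed = 30)
  expect_equal(fit$g, 0.2, tolerance = 1e-6)
  expect_equal(fit$h, 0.3, tolerance = 1e-6)
  expect_equal(fit$n_for(0.2 * log10(400) + 0.3), 400, tolerance = 1e-4)
  expect_equal(fit$n_for(fit$h), 1, tolerance = 1e-6)
  expect_gt(fit$r2, 0.9999)

  # learnable synthetic library: fitted slope is positive
  lib <- simulate_mcp_classes(
    list(mcp_class_profile("T7", 7, 300, 30, aa_profile(c("G", "A"), 0.35)),
         mcp_class_profile("T19", 19, 400, 30, aa_profile(c("F", "K"), 0.35))),
    50, seed = 31)
  scheme <- build_class_scheme(arch60, fit_hr, 0.09)
  feats <- featurize_library(lib)
  sizes <- c(10, 30, 60)
  av <- accuracy_vs_size(lib, scheme, n_splits_per_size = 5, seed = 32,
                         features = feats, sizes = sizes)
  lfit <- fit_log_accuracy(av[, c("n", "mean_accuracy")], n_boot = 50,
                           seed = 33)
  expect_gt(lfit$g, 0)
})

test_that("feature analysis flags informative features and covers all 22", {
  lib <- simulate_mcp_classes(separable_profiles(), 40, seed = 34)
  feats <- featurize_library(lib)
  classes <- lib$true_class
  set.seed(35)
  tr <- sample.int(nrow(lib), 60)
  model <- train_classifier(feats[tr, ], classes[tr], seed = 36)
  pa <- feature_analysis(model, feats[-tr, ], classes[-tr],
                         mode = "permutation", seed = 37)
  expect_equal(nrow(pa), 22L)
  # the class-defining composition features dominate the deltas
  top <- pa$feature[order(-pa$delta)][1:4]
  expect_true(any(c("freq_G", "freq_A", "freq_F", "freq_K", "length")
                  %in% top))
  # an uninformative (constant) feature has ~zero permutation delta
  const_feats <- cbind(feats, 0)
  colnames(const_feats)[23] <- "const"
  mc <- train_classifier(const_feats[tr, ], classes[tr], seed = 38)
  pc <- feature_analysis(mc, const_feats[-tr, ], classes[-tr],
                         mode = "permutation", seed = 39)
  expect_equal(pc$delta[pc$feature == "const"], 0, tolerance = 1e-9)

  da <- feature_analysis(model, feats[-tr, ], classes[-tr],
                         mode = "dropout", seed = 40)
  expect_equal(nrow(da), 22L)
  expect_true(all(is.finite(da$delta)))
})

test_that("clade feature profiling flags one-SD departures", {
  lib <- simulate_mcp_classes(separable_profiles(), 30, seed = 41)
  feats <- featurize_library(lib)
  whole <- clade_feature_profile(lib, lib$id, features = feats)
  expect_false(any(whole$significant))

  # a clade whose glycine frequency is shifted by two library SDs
  shifted <- feats
  idx <- 1:8
  shifted[idx, "freq_G"] <- shifted[idx, "freq_G"] +
    5 * sd(feats[, "freq_G"])
  prof <- clade_feature_profile(lib, lib$id[idx], features = shifted)
  expect_true(prof$significant[prof$feature == "freq_G"])

  one <- clade_feature_profile(lib, lib$id[1], features = feats)
  expect_equal(nrow(one), 22L)
  expect_error(clade_feature_profile(lib, character(0)), "empty")
  expect_error(clade_feature_profile(lib, "nope"), "subset")
})

test_that("per-query prediction cost is independent of training size", {
  lib <- simulate_mcp_classes(separable_profiles(), 40, seed = 42)
  feats <- featurize_library(lib)
  m_small <- train_classifier(feats[c(1:10, 41:50), ],
                              lib$true_class[c(1:10, 41:50)], seed = 43)
  m_large <- train_classifier(feats, lib$true_class, seed = 43)
  expect_identical(prediction_cost(m_small), prediction_cost(m_large))
})

test_that("model archives round-trip with their metadata", {
  lib <- simulate_mcp_classes(separable_profiles(), 10, seed = 44)
  feats <- featurize_library(lib)
  m <- train_classifier(feats, lib$true_class, seed = 45)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$feature_order, m$feature_order)
  expect_identical(back$version, m$version)
  expect_identical(predict(back, feats)$predicted_class,
                   predict(m, feats)$predicted_class)
})
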