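test_that("blast tabular loading symmetrizes by max and filters e-values", {
  path <- tempfile(fileext = ".tsv")
  write_toy_blast(path, list(
    c("a", "b", "85", "1e-5"),
    c("b", "a", "80", "1e-5"),
    c("a", "c", "70", "0.01"),   # above the e-value threshold
    c("a", "a", "100", "0")
  ))
  m <- load_similarity(path, ids = c("a", "b", "c"))
  expect_equal(m["a", "b"], 85)
  expect_equal(m["b", "a"], 85)
  expect_true(is.na(m["a", "c"]))
  expect_equal(m["a", "a"], 100)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t85", "x\ty\t80\t1"), bad)
  expect_error(load_similarity(bad), "line 1")
})

test_that("alignment-based similarity behaves like percent identity", {
  set.seed(77)
  s <- paste(sample(AA20, 100, replace = TRUE), collapse = "")
  s_mut <- s
  substr(s_mut, 50, 50) <- if (substr(s, 50, 50) == "A") "C" else "A"
  m <- align_similarity(c(x = s, y = s, z = s_mut))
  expect_equal(m["x", "y"], 100)
  expect_equal(m["x", "z"], 99, tolerance = 0.011)
  # matrix construction cost is quadratic in the number of sequences
  expect_equal(attr(m, "n_alignments"), 3L)
  m6 <- align_similarity(setNames(rep(s, 6), paste0("s", 1:6)))
  expect_equal(attr(m6, "n_alignments"), 15L)
  expect_error(align_similarity(c(a = "MA")), "at least 2")
})

test_that("unrelated low-complexity pairs are recorded as absent", {
  m <- align_similarity(c(a = strrep("GA", 60), b = strrep("FK", 60)))
  expect_true(is.na(m["a", "b"]))
})

test_that("nearest-neighbour prediction respects threshold and tie-break", {
  ids <- c("q", "t1", "t2", "t3")
  m <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
  diag(m) <- 100
  m["q", "t1"] <- m["t1", "q"] <- 92
  m["q", "t2"] <- m["t2", "q"] <- 70
  m["q", "t3"] <- m["t3", "q"] <- 92

  labels_a <- c(t1 = "19", t2 = "7", t3 = "9.33")
  p <- predict_nearest(m, labels_a, "q", min_similarity = 80)
  # tie at 92 between labels 19 and 9.33: smaller T wins
  expect_equal(p$label, "9.33")
  # the tie-break is invariant to training order
  p_rev <- predict_nearest(m, rev(labels_a), "q", min_similarity = 80)
  expect_equal(p_rev$label, "9.33")

  expect_equal(predict_nearest(m, labels_a["t1"], "q", 80)$label, "19")
  none <- predict_nearest(m, labels_a, "q", min_similarity = 95)
  expect_true(is.na(none$label))
  expect_error(predict_nearest(m, c(q = "7"), "q"), "training set")
  # prediction examines each training entry once: linear cost
  expect_equal(p$comparisons, 3L)
  expect_equal(predict_nearest(m, labels_a[1:2], "q")$comparisons, 2L)
})

test_that("identical-sequence trios are classified perfectly", {
  seqs <- c(rep(strrep("GAVLK", 40), 3), rep(strrep("FDERW", 40), 3),
            rep(strrep("HMNPQ", 40), 3))
  lib <- data.frame(id = paste0("s", 1:9),
                    t_label = rep(c("4", "7", "19"), each = 3),
                    stringsAsFactors = FALSE)
  m <- align_similarity(setNames(seqs, lib$id))
  ev <- evaluate_pm(lib, m, n_splits = 30, seed = 3, thresholds = c(0, 50))
  expect_equal(ev$accuracy, c(1, 1))
})

test_that("coverage is non-increasing and accuracy NA on zero calls", {
  lib <- simulate_mcp_classes(separable_profiles(), 12, seed = 14)
  m <- align_similarity(setNames(lib$sequence, lib$id))
  ev <- evaluate_pm(lib, m, n_splits = 40, seed = 15)
  expect_true(all(diff(ev$fraction_predicted) <= 1e-12))
  zero <- ev$fraction_predicted == 0
  expect_true(all(is.na(ev$accuracy[zero])))
  expect_true(all(ev$accuracy[!zero] >= 0 & ev$accuracy[!zero] <= 1))
  # random within-class sequences are matched to their own class
  expect_gt(ev$accuracy[1], 0.9)
})

test_that("relative T differences are summarized per similarity bin", {
  lib <- data.frame(id = c("a", "b", "c"),
                    t_label = c("7", "9.33", "7"),
                    stringsAsFactors = FALSE)
  ids <- lib$id
  m <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  diag(m) <- 100
  m["a", "b"] <- m["b", "a"] <- 90
  m["a", "c"] <- m["c", "a"] <- 90
  m["b", "c"] <- m["c", "b"] <- 10
  bins <- t_difference_by_bin(lib, m, bin_edges = c(0, 50, 100))
  hi <- bins[bins$lo == 50, ]
  # pairs (7, 9.33) and (7, 7): mean of 2.33/7 and 0
  expect_equal(hi$mean, mean(c(2.33 / 7, 0)), tolerance = 1e-3)
  expect_equal(hi$max, 2.33 / 7, tolerance = 1e-3)
  lo <- bins[bins$lo == 0, ]
  expect_equal(lo$mean, 2.33 / 7, tolerance = 1e-3)
  expect_error(t_difference_by_bin(lib, m, bin_edges = c(10, 100)),
               "cover")

  same <- data.frame(id = ids, t_label = rep("7", 3),
                     stringsAsFactors = FALSE)
  bins_same <- t_difference_by_bin(same, m, bin_edges = c(0, 50, 100))
  expect_true(all(bins_same$mean[bins_same$n_pairs > 0] == 0))
})

test_that("similarity correlates with label agreement on synthetic classes", {
  lib <- simulate_mcp_classes(separable_profiles(), 10, seed = 16)
  m <- align_similarity(setNames(lib$sequence, lib$id))
  bins <- t_difference_by_bin(lib, m, bin_edges = c(0, 60, 100))
  hi <- bins$mean[bins$lo == 60]
  lo <- bins$mean[bins$lo == 0]
  # pairs above 60% similarity are same-class (identical T)
  expect_true(is.na(hi) || hi <= lo)
})
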