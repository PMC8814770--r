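# Random-forest T-class classifier over the 22 sequence features, plus
# the T-class scheme construction, accuracy-scaling model and feature
# analyses.

#' Random-forest hyperparameters
#'
#' Defaults are the selected values of the original grid search: 250
#' trees, 4 features tried per split, maximum depth 20, minimum node
#' size to split 46, minimum terminal-node size 1, bootstrap resampling,
#' and balanced class weights.
#'
#' @param n_estimators Number of trees.
#' @param max_features Features tried per split (`mtry`).
#' @param max_depth Maximum tree depth.
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param min_samples_leaf Minimum terminal-node size.
#' @param bootstrap Sample with replacement per tree.
#' @param class_weight `"balanced"` or `NULL`.
#' @return A list of class `rf_hyperparams`.
#' @export
rf_hyperparams <- function(n_estimators = 250, max_features = 4,
                           max_depth = 20, min_samples_split = 46,
                           min_samples_leaf = 1, bootstrap = TRUE,
                           class_weight = "balanced") {
  stopifnot(n_estimators >= 1, max_features >= 1, max_depth >= 1,
            min_samples_split >= 2, min_samples_leaf >= 1)
  structure(list(n_estimators = n_estimators, max_features = max_features,
                 max_depth = max_depth,
                 min_samples_split = min_samples_split,
                 min_samples_leaf = min_samples_leaf,
                 bootstrap = bootstrap, class_weight = class_weight),
            class = "rf_hyperparams")
}

#' Build the T-class scheme
#'
#' Converts the continuous T-number axis into discrete classifier
#' classes: every architecture T-value below the jumbo cutoff gets a
#' genome-length range from [t_to_genome_range()]; T-values whose ranges
#' overlap (transitively) are merged into a single class; all T-values at
#' or above the cutoff form one jumbo class; an elongated class is added.
#'
#' @param architectures Architecture table ([enumerate_architectures()]).
#' @param fit A `g2t_fit`.
#' @param mre Assignment margin.
#' @param jumbo_min Jumbo cutoff (default 25; sparse sampling of large
#'   genomes does not support finer classes there).
#' @return An object of class `t_class_scheme`: list with `classes`
#'   (list of `class_id`, `member_t_values`, `genome_range`),
#'   `jumbo_class`, `elongated_class`, `jumbo_min`.
#' @export
build_class_scheme <- function(architectures, fit, mre, jumbo_min = 25) {
  tv <- sort(unique(architectures$t_value))
  small <- tv[tv < jumbo_min]
  jumbo <- tv[tv >= jumbo_min]
  ranges <- t(vapply(small, function(t) t_to_genome_range(fit, mre, t),
                     numeric(2)))
  # merge transitively overlapping [lo, hi] intervals (tv sorted)
  classes <- list()
  cur <- 1
  cur_hi <- ranges[1, 2]
  members <- small[1]
  for (i in seq_along(small)[-1]) {
    if (ranges[i, 1] <= cur_hi) {
      members <- c(members, small[i])
      cur_hi <- max(cur_hi, ranges[i, 2])
    } else {
      classes[[length(classes) + 1]] <- list(
        class_id = paste(format_t(members), collapse = "/"),
        member_t_values = members,
        genome_range = c(min(ranges[small %in% members, 1]), cur_hi))
      members <- small[i]
      cur_hi <- ranges[i, 2]
    }
  }
  classes[[length(classes) + 1]] <- list(
    class_id = paste(format_t(members), collapse = "/"),
    member_t_values = members,
    genome_range = c(min(ranges[small %in% members, 1]), cur_hi))
  jumbo_id <- paste0("T>=", jumbo_min)
  classes[[length(classes) + 1]] <- list(
    class_id = jumbo_id, member_t_values = jumbo,
    genome_range = c(t_to_genome_range(fit, mre, min(jumbo))[1], Inf))
  classes[[length(classes) + 1]] <- list(
    class_id = "elongated", member_t_values = numeric(0),
    genome_range = c(NA_real_, NA_real_))
  structure(list(classes = classes, jumbo_class = jumbo_id,
                 elongated_class = "elongated", jumbo_min = jumbo_min),
            class = "t_class_scheme")
}

#' Map library T labels to scheme classes
#'
#' @param scheme A `t_class_scheme`.
#' @param t_label Character T labels (`"7"`, `"9.33"`, `"elongated"`, ...).
#' @return Character class ids.
#' @export
t_label_to_class <- function(scheme, t_label) {
  vapply(t_label, function(lb) {
    if (lb == "elongated") return(scheme$elongated_class)
    t <- as.numeric(lb)
    if (t >= scheme$jumbo_min) return(scheme$jumbo_class)
    for (cl in scheme$classes) {
      if (length(cl$member_t_values) &&
          any(abs(cl$member_t_values - t) < 5e-3)) {
        return(cl$class_id)
      }
    }
    stop("T label ", lb, " matches no class in the scheme")
  }, character(1), USE.NAMES = FALSE)
}

scheme_members <- function(scheme, class_id) {
  for (cl in scheme$classes) if (cl$class_id == class_id) {
    return(cl$member_t_values)
  }
  stop("unknown class ", class_id)
}

# A predicted class is correct for an entry when the class's member
# T-value closest to the entry's library T lies within the margin
# (elongated must match exactly).
class_correct <- function(scheme, predicted_class, t_label, margin = 0.09) {
  mapply(function(pc, lb) {
    if (lb == "elongated" || pc == scheme$elongated_class) {
      return(pc == scheme$elongated_class && lb == "elongated")
    }
    t <- as.numeric(lb)
    members <- scheme_members(scheme, pc)
    if (!length(members)) return(FALSE)
    rep_t <- members[which.min(abs(members - t))]
    abs(rep_t - t) <= margin * t
  }, predicted_class, t_label, USE.NAMES = FALSE)
}

#' Train the random-forest T-class model
#'
#' Trains a seeded probability random forest (via `ranger`) on a feature
#' matrix and class labels. The hyperparameters map onto ranger as:
#' `n_estimators` -> `num.trees`, `max_features` -> `mtry`,
#' `max_depth` -> `max.depth`, `min_samples_split` -> `min.node.size`,
#' `min_samples_leaf` -> `min.bucket`, `bootstrap` -> `replace`; balanced
#' class weights are computed as n / (n_classes * class count). Training
#' runs single-threaded so that a fixed seed reproduces bit-for-bit.
#'
#' @param features Numeric matrix (rows = entries, 22 columns).
#' @param class_labels Character class labels (at least 2 distinct).
#' @param hyperparams An `rf_hyperparams` list.
#' @param seed Integer seed.
#' @return An object of class `mcp_rf_model` wrapping the ranger forest
#'   together with the feature order, class levels, hyperparameters,
#'   seed, and the training data (kept so that dropout analysis can
#'   retrain).
#' @export
train_classifier <- function(features, class_labels,
                             hyperparams = rf_hyperparams(), seed = 1) {
  if (length(unique(class_labels)) < 2) {
    stop("training set must contain at least 2 classes")
  }
  if (any(!is.finite(features))) stop("features must be finite")
  df <- as.data.frame(features)
  df$.class <- factor(class_labels)
  cw <- NULL
  if (identical(hyperparams$class_weight, "balanced")) {
    tab <- table(df$.class)
    cw <- as.numeric(length(class_labels) / (length(tab) * tab))
    names(cw) <- names(tab)
  }
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = hyperparams$n_estimators,
    mtry = min(hyperparams$max_features, ncol(features)),
    max.depth = hyperparams$max_depth,
    min.node.size = hyperparams$min_samples_split,
    min.bucket = hyperparams$min_samples_leaf,
    replace = hyperparams$bootstrap,
    class.weights = cw,
    probability = TRUE,
    seed = seed, num.threads = 1
  )
  structure(list(forest = forest, feature_order = colnames(features),
                 classes = levels(df$.class), hyperparams = hyperparams,
                 seed = seed, train_features = features,
                 train_labels = class_labels,
                 pka_hash = tryCatch(
                   unname(tools::md5sum(system.file(
                     "extdata", "pka_bjellqvist.tsv",
                     package = "capsidarch"))),
                   error = function(e) NA_character_),
                 version = "1"),
            class = "mcp_rf_model")
}

#' Predict T classes for a feature matrix
#'
#' @param object An `mcp_rf_model`.
#' @param features Numeric matrix with the model's feature columns.
#' @param ... Unused.
#' @return Data.frame with `predicted_class` and `class_probability`
#'   (the winning class's probability). The per-query prediction cost is
#'   set by the fixed ensemble size ([prediction_cost()]), independent of
#'   the training-set size.
#' @export
predict.mcp_rf_model <- function(object, features, ...) {
  features <- features[, object$feature_order, drop = FALSE]
  pr <- stats::predict(object$forest, data = as.data.frame(features),
                       num.threads = 1)$predictions
  win <- max.col(pr, ties.method = "first")
  data.frame(predicted_class = colnames(pr)[win],
             class_probability = pr[cbind(seq_len(nrow(pr)), win)],
             stringsAsFactors = FALSE)
}

#' Per-query prediction operation count
#'
#' The number of trees each query traverses: fixed by the ensemble size,
#' independent of how many entries the forest was trained on.
#'
#' @param model An `mcp_rf_model`.
#' @return Integer number of trees.
#' @export
prediction_cost <- function(model) model$forest$num.trees

#' Evaluate the random-forest classifier over repeated 80/20 splits
#'
#' For each random 80/20 split the model is trained on the training
#' portion and applied to the test portion. A prediction is correct when
#' the predicted class's member T-value closest to the entry's library T
#' lies within the margin (default 9%); an elongated prediction must
#' match exactly. Splits in which some class is absent from the training
#' portion are resampled (with a message).
#'
#' @param library Labelled library (`id`, `sequence` or precomputed
#'   features, `t_label`).
#' @param scheme A `t_class_scheme`.
#' @param hyperparams An `rf_hyperparams` list.
#' @param n_splits Number of random splits (default 1000).
#' @param seed Integer seed.
#' @param margin Relative correctness margin (default 0.09).
#' @param features Optional precomputed feature matrix (rows in library
#'   order); computed from sequences otherwise.
#' @param train_frac Training fraction (default 0.8).
#' @return A list with `overall_accuracy` (mean), `overall_sd`,
#'   `per_class_accuracy`, `confusion_mean`, `confusion_sd` (class-level
#'   row-normalized confusion matrices), `morphology_mean`,
#'   `morphology_sd` (icosahedral vs elongated), `n_splits`.
#' @export
evaluate_classifier <- function(library, scheme,
                                hyperparams = rf_hyperparams(),
                                n_splits = 1000, seed, margin = 0.09,
                                features = NULL, train_frac = 0.8) {
  if (missing(seed)) stop("seed is required")
  if (is.null(features)) features <- featurize_library(library)
  classes <- t_label_to_class(scheme, library$t_label)
  cls_levels <- sort(unique(classes))
  n <- nrow(library)
  n_train <- max(2, round(train_frac * n))
  set.seed(seed)
  acc <- numeric(n_splits)
  conf <- array(0, c(length(cls_levels), length(cls_levels), n_splits),
                dimnames = list(cls_levels, cls_levels, NULL))
  morph <- array(0, c(2, 2, n_splits),
                 dimnames = list(c("icosahedral", "elongated"),
                                 c("icosahedral", "elongated"), NULL))
  class_hits <- stats::setNames(numeric(length(cls_levels)), cls_levels)
  class_tot <- class_hits
  resampled <- 0
  for (s in seq_len(n_splits)) {
    for (try in 1:100) {
      tr <- sample.int(n, n_train)
      if (all(cls_levels %in% classes[tr])) break
      resampled <- resampled + 1
      if (try == 100) stop("could not draw a split containing every class")
    }
    model <- train_classifier(features[tr, , drop = FALSE], classes[tr],
                              hyperparams, seed = seed + s)
    pred <- predict.mcp_rf_model(model, features[-tr, , drop = FALSE])
    ok <- class_correct(scheme, pred$predicted_class, library$t_label[-tr],
                        margin)
    acc[s] <- mean(ok)
    true_cls <- classes[-tr]
    for (lv in cls_levels) {
      sel <- true_cls == lv
      class_tot[lv] <- class_tot[lv] + sum(sel)
      class_hits[lv] <- class_hits[lv] + sum(ok[sel])
    }
    tab <- table(factor(true_cls, cls_levels),
                 factor(pred$predicted_class, cls_levels))
    rs <- rowSums(tab)
    conf[, , s] <- sweep(tab, 1, pmax(rs, 1), "/")
    m_true <- ifelse(true_cls == scheme$elongated_class,
                     "elongated", "icosahedral")
    m_pred <- ifelse(pred$predicted_class == scheme$elongated_class,
                     "elongated", "icosahedral")
    mt <- table(factor(m_true, c("icosahedral", "elongated")),
                factor(m_pred, c("icosahedral", "elongated")))
    morph[, , s] <- sweep(mt, 1, pmax(rowSums(mt), 1), "/")
  }
  if (resampled > 0) {
    message(resampled, " splits resampled (class absent from training)")
  }
  list(overall_accuracy = mean(acc), overall_sd = stats::sd(acc),
       per_class_accuracy = ifelse(class_tot > 0, class_hits / class_tot,
                                   NA_real_),
       confusion_mean = apply(conf, 1:2, mean),
       confusion_sd = apply(conf, 1:2, stats::sd),
       morphology_mean = apply(morph, 1:2, mean),
       morphology_sd = apply(morph, 1:2, stats::sd),
       n_splits = n_splits)
}

#' Classifier accuracy as a function of training-set size
#'
#' Measures the mean correctness-margin accuracy for training sizes
#' n_i = n_lib * i/20, i = 1..19, each over `n_splits_per_size` random
#' splits (test set = remainder of the library).
#'
#' @inheritParams evaluate_classifier
#' @param n_splits_per_size Splits per training size.
#' @param sizes Optional explicit training sizes (overrides the i/20
#'   grid).
#' @return Data.frame with columns `n`, `mean_accuracy`, `sd`.
#' @export
accuracy_vs_size <- function(library, scheme,
                             hyperparams = rf_hyperparams(),
                             n_splits_per_size = 1000, seed, margin = 0.09,
                             features = NULL, sizes = NULL) {
  if (missing(seed)) stop("seed is required")
  if (nrow(library) < 40) stop("library too small for a size scan")
  if (is.null(features)) features <- featurize_library(library)
  classes <- t_label_to_class(scheme, library$t_label)
  n <- nrow(library)
  if (is.null(sizes)) sizes <- unique(pmax(2, round(n * (1:19) / 20)))
  set.seed(seed)
  rows <- lapply(sizes, function(ni) {
    a <- vapply(seq_len(n_splits_per_size), function(s) {
      for (try in 1:100) {
        tr <- sample.int(n, ni)
        if (length(unique(classes[tr])) >= 2) break
      }
      model <- train_classifier(features[tr, , drop = FALSE], classes[tr],
                                hyperparams, seed = seed + ni * 1000 + s)
      pred <- predict.mcp_rf_model(model, features[-tr, , drop = FALSE])
      mean(class_correct(scheme, pred$predicted_class,
                         library$t_label[-tr], margin))
    }, numeric(1))
    c(mean(a), stats::sd(a))
  })
  rows <- do.call(rbind, rows)
  data.frame(n = sizes, mean_accuracy = rows[, 1], sd = rows[, 2])
}

#' Fit the logarithmic accuracy-scaling model
#'
#' Fits \eqn{MACC(n) = g \log_{10} n + h} to an [accuracy_vs_size()]
#' table by robust (soft-L1) least squares, with percentile-bootstrap
#' confidence intervals, and provides the inversion
#' \eqn{n(A) = 10^{(A - h)/g}} to project the training size needed for a
#' target accuracy.
#'
#' @param table Data.frame with columns `n`, `mean_accuracy`.
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed for the bootstrap.
#' @return List of class `log_accuracy_fit`: `g`, `h`, `r2`, `ci`, and
#'   `n_for(target_accuracy)`.
#' @export
fit_log_accuracy <- function(table, n_boot = 1000, seed = NULL) {
  x <- log10(table$n)
  y <- table$mean_accuracy
  pred_fn <- function(par, x) par[1] * x + par[2]
  start <- stats::setNames(rev(ols2(x, y)), c("g", "h"))
  fit <- robust_ls(pred_fn, start, x, y)
  boot <- robust_ls_bootstrap(pred_fn, fit$par, x, y, n_boot = n_boot,
                              seed = seed)
  g <- unname(fit$par["g"]); h <- unname(fit$par["h"])
  structure(list(g = g, h = h, r2 = fit$r2, ci = boot$ci,
                 n_for = function(target_accuracy) {
                   10^((target_accuracy - h) / g)
                 }),
            class = "log_accuracy_fit")
}

#' Per-feature importance by permutation or dropout
#'
#' Permutation: each feature column of the held-out set is shuffled in
#' turn and the drop in accuracy recorded. Dropout: the model is
#' retrained without the feature (using the training data stored in the
#' model) and the held-out accuracy drop recorded. Both are seeded.
#' Deltas are reported for all 22 features; positive delta = accuracy
#' lost without the feature's information.
#'
#' @param model A trained `mcp_rf_model`.
#' @param test_features Held-out feature matrix.
#' @param test_classes Held-out true class labels.
#' @param mode `"permutation"` or `"dropout"`.
#' @param seed Integer seed.
#' @return Data.frame with columns `feature`, `baseline_accuracy`,
#'   `accuracy`, `delta`.
#' @export
feature_analysis <- function(model, test_features, test_classes,
                             mode = c("permutation", "dropout"), seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  base_pred <- predict.mcp_rf_model(model, test_features)
  baseline <- mean(base_pred$predicted_class == test_classes)
  feats <- model$feature_order
  acc <- vapply(feats, function(f) {
    if (mode == "permutation") {
      perm <- test_features
      perm[, f] <- sample(perm[, f])
      mean(predict.mcp_rf_model(model, perm)$predicted_class == test_classes)
    } else {
      keep <- setdiff(feats, f)
      m2 <- train_classifier(model$train_features[, keep, drop = FALSE],
                             model$train_labels, model$hyperparams,
                             seed = seed)
      mean(predict.mcp_rf_model(m2, test_features[, keep, drop = FALSE])$
             predicted_class == test_classes)
    }
  }, numeric(1))
  data.frame(feature = feats, baseline_accuracy = baseline,
             accuracy = unname(acc), delta = baseline - unname(acc),
             stringsAsFactors = FALSE)
}

#' Feature profile of a clade against the library
#'
#' Compares the mean of each of the 22 features within a clade to the
#' library-wide mean; a feature is flagged significant when the clade
#' mean departs from the library mean by more than one library standard
#' deviation.
#'
#' @param library Labelled library with `id` and `sequence`.
#' @param clade_member_ids Ids of the clade members (subset of library
#'   ids, non-empty).
#' @param features Optional precomputed feature matrix.
#' @return Data.frame with columns `feature`, `clade_mean`,
#'   `library_mean`, `library_sd`, `significant`.
#' @export
clade_feature_profile <- function(library, clade_member_ids,
                                  features = NULL) {
  if (length(clade_member_ids) == 0) stop("clade is empty")
  if (!all(clade_member_ids %in% library$id)) {
    stop("clade ids must be a subset of library ids")
  }
  if (is.null(features)) features <- featurize_library(library)
  in_clade <- library$id %in% clade_member_ids
  lib_mean <- colMeans(features)
  lib_sd <- apply(features, 2, stats::sd)
  clade_mean <- colMeans(features[in_clade, , drop = FALSE])
  data.frame(feature = colnames(features),
             clade_mean = unname(clade_mean),
             library_mean = unname(lib_mean),
             library_sd = unname(lib_sd),
             significant = unname(abs(clade_mean - lib_mean) > lib_sd),
             stringsAsFactors = FALSE)
}

#' Save / load a trained model archive
#'
#' The archive embeds the forest, feature order, class scheme levels,
#' hyperparameters, pKa table hash, seed and a format version.
#'
#' @param model An `mcp_rf_model`.
#' @param path Output path (`.rds`).
#' @return `path` invisibly (`save_model`); an `mcp_rf_model`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mcp_rf_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mcp_rf_model")) stop("not a model archive")
  model
}
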