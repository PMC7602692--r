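#' Random-forest specification
#'
#' Forests of 100 trees grown to purity (Gini impurity zero at every leaf)
#' on bootstrap resamples; the forest prediction is the mode of the tree
#' predictions. The number of candidate features per split defaults to the
#' square-root heuristic.
#'
#' @param n_trees trees per forest (default 100).
#' @param mtry candidate features per split; `NULL` for `floor(sqrt(p))`.
#' @param min_node_size minimal node size; 1 grows trees to purity.
#' @return An object of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 100, mtry = NULL, min_node_size = 1) {
  structure(list(n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size),
            class = "forest_spec")
}

roster_from <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x[[1]]$subject_id)) {
    x <- data.frame(
      subject_id = vapply(x, `[[`, "", "subject_id"),
      activity = vapply(x, `[[`, "", "activity"))
  }
  unique(x[, c("subject_id", "activity")])
}

#' Build subject-wise train/test assignments
#'
#' Draws `n_assignments` distinct training sets of `n_train` subjects each,
#' restricted to subjects who completed all required activities; every other
#' subject (including incomplete ones) forms the test set of that
#' assignment. Each assignment carries `n_random_states` forest seeds, all
#' derived deterministically from `seed`.
#'
#' @param roster a data frame with columns `subject_id` and `activity` (one
#'   row per bout or per window), a list of recordings, or a feature matrix.
#' @param n_assignments number of train/test splits (default 5).
#' @param n_train training subjects per assignment (default 6).
#' @param n_random_states forest seeds per assignment (default 20).
#' @param seed master seed.
#' @param required_activities activities a subject must have completed to be
#'   eligible for training (default all nine).
#' @return List of assignment plans, each a list with `assignment_id`,
#'   `train_subjects`, `test_subjects`, `random_states`.
#' @export
make_assignments <- function(roster, n_assignments = 5, n_train = 6,
                             n_random_states = 20, seed = 1,
                             required_activities = activities()) {
  roster <- roster_from(roster)
  subjects <- unique(roster$subject_id)
  complete <- subjects[vapply(subjects, function(s) {
    all(required_activities %in% roster$activity[roster$subject_id == s])
  }, logical(1))]
  if (length(complete) < n_train) {
    stop("need at least ", n_train, " subjects with all required activities, ",
         "found ", length(complete))
  }
  set.seed(seed)
  seen <- character(0)
  plans <- vector("list", n_assignments)
  for (a in seq_len(n_assignments)) {
    for (try in 1:1000) {
      tr <- sort(sample(complete, n_train))
      key <- paste(tr, collapse = "|")
      if (!key %in% seen || choose(length(complete), n_train) < n_assignments) {
        break
      }
    }
    seen <- c(seen, key)
    plans[[a]] <- list(
      assignment_id = a,
      train_subjects = tr,
      test_subjects = sort(setdiff(subjects, tr)),
      random_states = sample.int(.Machine$integer.max, n_random_states))
  }
  plans
}

#' Train one random forest
#'
#' Bagged trees with Gini splits grown to purity (via \pkg{ranger});
#' impurity importance is recorded per feature. Prediction aggregates the
#' individual tree votes and breaks exact ties by lexicographic activity
#' label.
#'
#' @param x numeric feature matrix or data frame (no non-finite values).
#' @param y activity labels (factor or character); at least 2 classes.
#' @param spec a [forest_spec()].
#' @param random_state integer seed for bootstrap and split sampling.
#' @return An object of class `ar_forest`.
#' @export
train_forest <- function(x, y, spec = forest_spec(), random_state = 1) {
  x <- as.data.frame(x)
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  if (nlevels(y) < 2) stop("training labels must contain at least 2 classes")
  if (!all(vapply(x, function(c) all(is.finite(c)), logical(1)))) {
    stop("training features must be finite")
  }
  mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(ncol(x)))) else spec$mtry
  fit <- ranger::ranger(
    x = x, y = y, num.trees = spec$n_trees, mtry = mtry,
    min.node.size = spec$min_node_size, replace = TRUE,
    importance = "impurity", splitrule = "gini",
    seed = random_state, num.threads = 1)
  structure(list(fit = fit, levels = levels(y), spec = spec,
                 random_state = random_state),
            class = "ar_forest")
}

#' @param object an `ar_forest`.
#' @param newdata feature matrix or data frame with the training columns.
#' @param ... unused.
#' @rdname train_forest
#' @export
predict.ar_forest <- function(object, newdata, ...) {
  pr <- predict(object$fit, data = as.data.frame(newdata),
                predict.all = TRUE, num.threads = 1)
  votes <- pr$predictions                     # n x n_trees class codes
  lv <- object$fit$forest$levels
  ord <- order(lv)                            # lexicographic tie-break
  counts <- apply(votes, 1, tabulate, nbins = length(lv))
  counts <- counts[ord, , drop = FALSE]
  factor(lv[ord][apply(counts, 2, which.max)], levels = sort(lv))
}

#' Evaluate random forests under the subject-wise protocol
#'
#' Trains one forest per (assignment, random state) pair — 100 forests for
#' the default 5 assignments x 20 states — always on training-subject
#' windows only, and evaluates on the held-out subjects' windows. Reports
#' per-forest accuracy (correct windows / total test windows), the
#' row-normalized confusion matrix averaged over forests, per-activity
#' sensitivity (TP / (TP + FN)), and mean impurity importance per feature.
#'
#' @param features a feature matrix from [extract_feature_matrix()] (or any
#'   data frame with `subject_id`, `activity` and feature columns).
#' @param plans assignments from [make_assignments()].
#' @param spec a [forest_spec()].
#' @return An object of class `ar_eval`.
#' @export
evaluate_round <- function(features, plans, spec = forest_spec()) {
  ids <- feature_ids(features)
  labs <- sort(unique(c(features$activity, activities())))
  n_lab <- length(labs)
  conf_sum <- matrix(0, n_lab, n_lab, dimnames = list(labs, labs))
  conf_n <- matrix(0, n_lab, n_lab, dimnames = list(labs, labs))
  imp_sum <- stats::setNames(numeric(length(ids)), ids)
  rows <- list()
  for (plan in plans) {
    if (length(intersect(plan$train_subjects, plan$test_subjects)) > 0) {
      stop("internal error: subject leakage between train and test sets")
    }
    tr <- features$subject_id %in% plan$train_subjects
    te <- features$subject_id %in% plan$test_subjects
    x_tr <- features[tr, ids, drop = FALSE]
    y_tr <- features$activity[tr]
    x_te <- features[te, ids, drop = FALSE]
    y_te <- factor(features$activity[te], levels = labs)
    for (rs in plan$random_states) {
      forest <- train_forest(x_tr, y_tr, spec, random_state = rs)
      pred <- factor(as.character(predict(forest, x_te)), levels = labs)
      acc <- mean(pred == y_te)
      tab <- table(actual = y_te, predicted = pred)
      support <- rowSums(tab)
      norm <- tab / ifelse(support > 0, support, 1)
      nz <- support > 0
      conf_sum[nz, ] <- conf_sum[nz, ] + norm[nz, ]
      conf_n[nz, ] <- conf_n[nz, ] + 1
      imp_sum <- imp_sum + forest$fit$variable.importance[ids]
      rows[[length(rows) + 1L]] <- data.frame(
        assignment = plan$assignment_id, random_state = rs, accuracy = acc,
        n_test = sum(te))
    }
  }
  forests <- do.call(rbind, rows)
  confusion <- conf_sum / ifelse(conf_n > 0, conf_n, 1)
  # display in canonical activity order
  disp <- intersect(activities(), labs)
  confusion <- confusion[disp, disp]
  structure(list(
    forests = forests,
    accuracy_mean = mean(forests$accuracy),
    accuracy_min = min(forests$accuracy),
    accuracy_max = max(forests$accuracy),
    confusion = confusion,
    sensitivity = diag(confusion),
    importance = imp_sum / nrow(forests),
    n_features = length(ids), n_forests = nrow(forests), spec = spec),
    class = "ar_eval")
}

#' @export
print.ar_eval <- function(x, ...) {
  cat(sprintf("<ar_eval> %d forests, %d features: accuracy %.3f (min %.3f, max %.3f)\n",
              x$n_forests, x$n_features, x$accuracy_mean, x$accuracy_min,
              x$accuracy_max))
  invisible(x)
}

#' @export
summary.ar_eval <- function(object, digits = 3, ...) {
  print(object)
  cat("\nPer-activity sensitivity:\n")
  print(round(object$sensitivity, digits))
  cat("\nConfusion (rows = actual, row-normalized, averaged over forests):\n")
  print(round(object$confusion, digits))
  invisible(object)
}

#' @export
plot.ar_eval <- function(x, main = "Confusion matrix", ...) {
  m <- x$confusion
  k <- nrow(m)
  image(seq_len(k), seq_len(k), t(m[k:1, ]), zlim = c(0, 1),
        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "predicted", ylab = "actual", axes = FALSE, main = main, ...)
  axis(1, seq_len(k), colnames(m), las = 2, cex.axis = 0.7)
  axis(2, seq_len(k), rev(rownames(m)), las = 2, cex.axis = 0.7)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    text(j, k - i + 1, sprintf("%.2f", m[i, j]), cex = 0.6)
  }
  invisible(x)
}

#' Recursive feature elimination
#'
#' Evaluates the current feature set, removes the single feature with the
#' smallest mean impurity importance across the round's forests (ties broken
#' by catalog order), and repeats until `min_features` remain: starting from
#' m features this runs `m - min_features + 1` evaluation rounds.
#'
#' @inheritParams evaluate_round
#' @param min_features stop when this many features remain (default 1).
#' @param keep_evals keep every round's full `ar_eval` (default FALSE; the
#'   trace alone is usually enough and much lighter).
#' @return An object of class `ar_elim`: `trace` is a data frame with one
#'   row per round (`n_features`, accuracy summaries, `removed`), `evals`
#'   the retained evaluations.
#' @export
rank_and_eliminate <- function(features, plans, spec = forest_spec(),
                               min_features = 1, keep_evals = FALSE) {
  meta <- c("subject_id", "activity", "window_start_s")
  current <- feature_ids(features)
  stopifnot(min_features >= 1, length(current) >= min_features)
  rows <- list()
  evals <- list()
  repeat {
    sub <- features[, c(intersect(meta, names(features)), current)]
    attr(sub, "feature_ids") <- current
    res <- evaluate_round(sub, plans, spec)
    removed <- NA_character_
    if (length(current) > min_features) {
      imp <- res$importance[current]
      removed <- current[order(imp, seq_along(current))[1]]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      round = length(rows) + 1L, n_features = length(current),
      accuracy_mean = res$accuracy_mean, accuracy_min = res$accuracy_min,
      accuracy_max = res$accuracy_max, removed = removed)
    if (keep_evals) evals[[length(evals) + 1L]] <- res
    if (length(current) <= min_features) break
    current <- setdiff(current, removed)
  }
  structure(list(trace = do.call(rbind, rows), evals = evals,
                 final_features = current),
            class = "ar_elim")
}

#' @export
print.ar_elim <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<ar_elim> %d rounds, %d -> %d features; accuracy %.3f -> %.3f\n",
              nrow(tr), tr$n_features[1], tr$n_features[nrow(tr)],
              tr$accuracy_mean[1], tr$accuracy_mean[nrow(tr)]))
  invisible(x)
}

#' @export
plot.ar_elim <- function(x, ...) {
  tr <- x$trace
  plot(tr$n_features, tr$accuracy_mean, type = "b", pch = 16,
       xlab = "number of features", ylab = "mean accuracy",
       xlim = rev(range(tr$n_features)), ...)
  invisible(x)
}

#' Choose the optimum window length from a sweep
#'
#' The accuracy-versus-length curve typically rises steeply and then
#' flattens; to preserve temporal resolution the optimum is defined as the
#' smallest length whose mean accuracy is within `delta` of the sweep
#' maximum.
#'
#' @param results data frame with columns `length_s` and `accuracy_mean`.
#' @param delta plateau tolerance on accuracy (default 0.01).
#' @return The selected window length in seconds.
#' @export
select_optimum_window <- function(results, delta = 0.01) {
  ok <- results$accuracy_mean >= max(results$accuracy_mean) - delta
  min(results$length_s[ok])
}

#' Sweep over analysis window lengths
#'
#' Re-extracts features and re-evaluates forests for each candidate window
#' length with a fixed sensor configuration and fixed subject-wise
#' assignments.
#'
#' @param recordings list of [pressure_recording()]s.
#' @param lengths window lengths in seconds (default the 1-60 s grid).
#' @param config a [sensor_config()] or site vector (default all 7 sites).
#' @param spec a [forest_spec()].
#' @param plans assignments; built from the recordings' roster when `NULL`.
#' @param delta plateau tolerance for [select_optimum_window()].
#' @param control a [feature_control()].
#' @param ... passed to [make_assignments()] when `plans` is `NULL`.
#' @return An object of class `ar_sweep`: `results` (one row per length),
#'   `optimum` (selected length, s), `evals`.
#' @export
window_length_sweep <- function(recordings, lengths = c(1, seq(5, 60, 5)),
                                config = 1:7, spec = forest_spec(),
                                plans = NULL, delta = 0.01,
                                control = feature_control(), ...) {
  if (is.null(plans)) plans <- make_assignments(roster_from(recordings), ...)
  evals <- lapply(lengths, function(L) {
    fm <- extract_feature_matrix(recordings, config, L, control)
    evaluate_round(fm, plans, spec)
  })
  results <- data.frame(
    length_s = lengths,
    n_windows = NA_integer_,
    accuracy_mean = vapply(evals, `[[`, 0, "accuracy_mean"),
    accuracy_min = vapply(evals, `[[`, 0, "accuracy_min"),
    accuracy_max = vapply(evals, `[[`, 0, "accuracy_max"))
  structure(list(results = results,
                 optimum = select_optimum_window(results, delta),
                 delta = delta, evals = evals),
            class = "ar_sweep")
}

#' @export
print.ar_sweep <- function(x, ...) {
  cat(sprintf("<ar_sweep> %d window lengths; optimum %g s (plateau tolerance %g)\n",
              nrow(x$results), x$optimum, x$delta))
  print(x$results[, c("length_s", "accuracy_mean", "accuracy_min",
                      "accuracy_max")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.ar_sweep <- function(x, ...) {
  r <- x$results
  plot(r$length_s, r$accuracy_mean, type = "b", pch = 16,
       xlab = "window length (s)", ylab = "mean accuracy", ...)
  graphics::abline(v = x$optimum, lty = 2)
  invisible(x)
}

#' Sweep over sensor configurations
#'
#' Independently evaluates each configuration at a fixed window length;
#' every configuration uses its own available feature set.
#'
#' @inheritParams window_length_sweep
#' @param configs list of [sensor_config()]s (or site vectors).
#' @param window_s fixed window length in seconds.
#' @return An object of class `ar_csweep` with `results` (one row per
#'   configuration: label, number of sites, feature count, accuracy
#'   summaries) and `evals`.
#' @export
configuration_sweep <- function(recordings, configs, window_s,
                                spec = forest_spec(), plans = NULL,
                                control = feature_control(), ...) {
  stopifnot(length(configs) >= 1)
  configs <- lapply(configs, as_sensor_config)
  if (is.null(plans)) plans <- make_assignments(roster_from(recordings), ...)
  evals <- lapply(configs, function(cfg) {
    fm <- extract_feature_matrix(recordings, cfg, window_s, control)
    evaluate_round(fm, plans, spec)
  })
  results <- data.frame(
    label = vapply(configs, `[[`, "", "label"),
    n_sites = vapply(configs, function(c) length(c$sites), 0L),
    n_features = vapply(configs, count_features, 0L),
    accuracy_mean = vapply(evals, `[[`, 0, "accuracy_mean"),
    accuracy_min = vapply(evals, `[[`, 0, "accuracy_min"),
    accuracy_max = vapply(evals, `[[`, 0, "accuracy_max"))
  structure(list(results = results, configs = configs, evals = evals,
                 window_s = window_s),
            class = "ar_csweep")
}

#' @export
print.ar_csweep <- function(x, ...) {
  cat(sprintf("<ar_csweep> %d sensor configurations at %g s windows\n",
              nrow(x$results), x$window_s))
  print(x$results, row.names = FALSE)
  invisible(x)
}
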