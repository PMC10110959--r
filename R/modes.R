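numeric_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    storage.mode(features) <- "double"
    return(features)
  }
  as.matrix(dplyr::select(tibble::as_tibble(features),
                          dplyr::where(is.numeric)))
}

#' Per-point silhouette diagnostics
#'
#' For every point, the mean Euclidean distance to its own cluster
#' \eqn{D_W(i) = \frac{1}{|C_I|}\sum_{j \in C_I} d(i,j)} (the average runs
#' over all members including \eqn{i} itself, so the divisor is the full
#' cluster size), the minimum over other clusters of the mean distance
#' \eqn{D_D(i)}, and the silhouette
#' \eqn{s(i) = (D_D(i) - D_W(i)) / \max(D_W(i), D_D(i)) \in [-1, 1]}.
#' Note the divisor convention differs from the common
#' \eqn{|C_I| - 1} definition used by some libraries.
#'
#' @param features Numeric matrix or data frame of points (rows) by
#'   features (columns); non-numeric columns are dropped.
#' @param labels Cluster assignment, one per row (>= 2 distinct values).
#' @return A tibble with `point`, `cluster`, `d_within`, `d_between`,
#'   `score`; the mean silhouette is attached as attribute
#'   `"mean_score"`.
#' @export
silhouette_scores <- function(features, labels) {
  x <- numeric_feature_matrix(features)
  labels <- as.vector(labels)
  stopifnot(nrow(x) == length(labels))
  lev <- sort(unique(labels))
  if (length(lev) < 2) {
    abort("silhouette undefined for a single cluster",
          class = "modewalk_score_error")
  }
  d <- as.matrix(dist(x))
  ind <- vapply(lev, function(l) as.numeric(labels == l),
                numeric(length(labels)))
  sizes <- colSums(ind)
  mean_d <- sweep(d %*% ind, 2, sizes, "/")  # point x cluster mean distance
  li <- match(labels, lev)
  dw <- mean_d[cbind(seq_along(labels), li)]
  other <- mean_d
  other[cbind(seq_along(labels), li)] <- Inf
  dd <- apply(other, 1, min)
  denom <- pmax(dw, dd)
  s <- ifelse(denom > 0, (dd - dw) / denom, 0)
  out <- tibble::tibble(point = seq_along(labels), cluster = labels,
                        d_within = dw, d_between = dd, score = s)
  attr(out, "mean_score") <- mean(s)
  out
}

#' Mean-silhouette scan over candidate cluster counts
#'
#' Standardizes the feature columns (z-score per feature), fits K-means at
#' every `k` in `k_range` (multiple random restarts under a fixed seed)
#' and records the mean silhouette score; the maximizing `k` is the
#' selected cluster count.
#'
#' @param features Data frame or matrix of per-segment features; only
#'   numeric columns are used.
#' @param k_range Candidate cluster counts (default `2:8`).
#' @param seed Integer seed for the K-means restarts.
#' @param nstart Random restarts per `k` (default 25).
#' @return A tibble of class `"silhouette_scan"` with columns `k` and
#'   `mean_silhouette`; the selected count is attribute `"best_k"`.
#' @export
scan_cluster_count <- function(features, k_range = 2:8, seed = 1,
                               nstart = 25) {
  x <- numeric_feature_matrix(features)
  if (nrow(x) <= max(k_range)) {
    abort("need more points than the largest candidate k",
          class = "modewalk_size_error")
  }
  if (any(apply(x, 2, sd) == 0) || nrow(unique(x)) <= max(k_range)) {
    abort("degenerate features: not enough distinct points to cluster",
          class = "modewalk_clustering_error")
  }
  xs <- scale(x)
  scores <- vapply(k_range, function(k) {
    km <- with_seed(derive_seed(seed, k),
                    kmeans(xs, centers = k, nstart = nstart, iter.max = 100))
    attr(silhouette_scores(xs, km$cluster), "mean_score")
  }, numeric(1))
  out <- tibble::tibble(k = as.integer(k_range), mean_silhouette = scores)
  attr(out, "best_k") <- out$k[which.max(out$mean_silhouette)]
  class(out) <- c("silhouette_scan", class(out))
  out
}

#' Name the three clusters as migration modes
#'
#' Assigns `FP` to the cluster with the highest mean energy; of the
#' remaining two, the higher mean asphericity becomes `SP` and the lower
#' `SD` (energy separates the fast mode; asphericity separates diffusive
#' from persistent slow motion). Naming is invariant to cluster index
#' permutation.
#'
#' @param features Tibble containing `energy` and `asphericity` columns
#'   (original units).
#' @param labels Cluster assignment with exactly 3 distinct values.
#' @param tol Relative tolerance below which competing cluster means are
#'   declared ambiguous.
#' @return Named character vector mapping cluster label to mode name.
#' @export
name_modes <- function(features, labels, tol = 1e-8) {
  lev <- sort(unique(labels))
  if (length(lev) != 3) {
    abort("mode naming requires exactly 3 clusters",
          class = "modewalk_naming_error")
  }
  m <- tibble::tibble(cluster = labels,
                      energy = features$energy,
                      asphericity = features$asphericity) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(energy = mean(.data$energy),
                     asphericity = mean(.data$asphericity))
  rel_gap <- function(a, b) abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)
  e_sorted <- sort(m$energy, decreasing = TRUE)
  if (rel_gap(e_sorted[1], e_sorted[2]) < tol) {
    abort(paste0("ambiguous mode naming: top cluster energies tie (",
                 paste(signif(e_sorted, 6), collapse = ", "), ")"),
          class = "modewalk_naming_error")
  }
  fp <- m$cluster[which.max(m$energy)]
  rest <- m[m$cluster != fp, ]
  if (rel_gap(rest$asphericity[1], rest$asphericity[2]) < tol) {
    abort("ambiguous mode naming: slow-cluster asphericities tie",
          class = "modewalk_naming_error")
  }
  sp <- rest$cluster[which.max(rest$asphericity)]
  sd_ <- rest$cluster[which.min(rest$asphericity)]
  out <- c("SD", "SP", "FP")
  names(out) <- c(as.character(sd_), as.character(sp), as.character(fp))
  out[order(names(out))]
}

default_xgb_grid <- function() {
  expand.grid(max_depth = c(3L, 6L), eta = c(0.1, 0.3),
              nrounds = c(100L, 300L))
}

#' Fit the hybrid mode-discovery model
#'
#' The hybrid kernel: (1) z-score the five features; (2) K-means with `k`
#' clusters (silhouette-selected when `k = NULL`) provides pseudo-labels;
#' (3) a gradient-boosted tree classifier (XGBoost) is trained on a
#' random fraction of the pseudo-labeled segments, with 5-fold
#' cross-validated selection over a small hyperparameter grid (tree depth
#' 3/6, learning rate 0.1/0.3, 100/300 trees); (4) agreement with the
#' pseudo-labels on the held-out remainder and per-feature importances
#' are recorded; (5) when `k = 3` the clusters are named SD/SP/FP via
#' [name_modes()].
#'
#' @param features Tibble with the five feature columns (`rg`,
#'   `asphericity`, `energy`, `rete`, `var_theta`), e.g. from
#'   [track_features()]; extra columns are carried but unused.
#' @param k Cluster count; `NULL` selects it by [scan_cluster_count()].
#' @param train_fraction Fraction of segments used for classifier
#'   training (default 0.366).
#' @param train_count Absolute training-set size; overrides
#'   `train_fraction` when given.
#' @param grid Hyperparameter grid (data frame with `max_depth`, `eta`,
#'   `nrounds`).
#' @param nfold Cross-validation folds (default 5).
#' @param seed Integer seed controlling clustering, the split and
#'   training.
#' @return An object of class `"mode_model"`; see [tidy.mode_model()] and
#'   [glance.mode_model()].
#' @export
fit_modes <- function(features, k = NULL, train_fraction = 0.366,
                      train_count = NULL, grid = default_xgb_grid(),
                      nfold = 5, seed = 1) {
  fn <- feature_names()
  missing_cols <- setdiff(fn, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("features are missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "modewalk_format_error")
  }
  x <- as.matrix(features[fn])
  n <- nrow(x)
  scan <- NULL
  if (is.null(k)) {
    scan <- scan_cluster_count(x, seed = seed)
    k <- attr(scan, "best_k")
  }
  xs <- scale(x)
  centers_attr <- attr(xs, "scaled:center")
  scales_attr <- attr(xs, "scaled:scale")
  km <- with_seed(derive_seed(seed, 1000 + k),
                  kmeans(xs, centers = k, nstart = 25, iter.max = 100))
  pseudo <- km$cluster
  n_train <- if (!is.null(train_count)) as.integer(train_count)
             else round(train_fraction * n)
  if (n_train < k || n_train >= n) {
    abort("training split must be non-empty and leave held-out segments",
          class = "modewalk_size_error")
  }
  train_idx <- with_seed(derive_seed(seed, 2), sample.int(n, n_train))
  if (length(unique(pseudo[train_idx])) < k) {
    abort("a pseudo-class is absent from the training split",
          class = "modewalk_stratification_error")
  }
  dtrain <- xgboost::xgb.DMatrix(xs[train_idx, , drop = FALSE],
                                 label = pseudo[train_idx] - 1)
  cv_tbl <- purrr::pmap(unique(grid[c("max_depth", "eta")]),
                        function(max_depth, eta) {
    pars <- list(objective = "multi:softmax", num_class = k,
                 max_depth = max_depth, eta = eta, nthread = 1,
                 eval_metric = "merror")
    cv <- with_seed(derive_seed(seed, 3), xgboost::xgb.cv(
      params = pars, data = dtrain, nrounds = max(grid$nrounds),
      nfold = nfold, verbose = FALSE))
    log <- cv$evaluation_log
    tibble::tibble(max_depth = max_depth, eta = eta,
                   nrounds = sort(unique(grid$nrounds)),
                   cv_error = log$test_merror_mean[
                     sort(unique(grid$nrounds))])
  }) |> purrr::list_rbind()
  best <- cv_tbl[which.min(cv_tbl$cv_error), ]
  pars <- list(objective = "multi:softmax", num_class = k,
               max_depth = best$max_depth, eta = best$eta, nthread = 1,
               eval_metric = "merror")
  booster <- with_seed(derive_seed(seed, 4), xgboost::xgb.train(
    params = pars, data = dtrain, nrounds = best$nrounds, verbose = 0))
  pred_all <- predict(booster, xgboost::xgb.DMatrix(xs)) + 1
  heldout <- setdiff(seq_len(n), train_idx)
  heldout_agreement <- mean(pred_all[heldout] == pseudo[heldout])
  train_agreement <- mean(pred_all[train_idx] == pseudo[train_idx])
  imp_raw <- xgboost::xgb.importance(model = booster)
  importance <- stats::setNames(numeric(length(fn)), fn)
  importance[imp_raw$Feature] <- imp_raw$Gain
  mode_map <- if (k == 3) name_modes(features, pseudo)
              else stats::setNames(paste0("M", seq_len(k)), seq_len(k))
  structure(list(
    k = k, feature_names = fn,
    center = centers_attr, scale = scales_attr,
    centers_scaled = km$centers, pseudo_labels = pseudo,
    booster = booster, params = best, cv_results = cv_tbl,
    importance = importance, mode_map = mode_map,
    heldout_agreement = heldout_agreement,
    train_agreement = train_agreement,
    n = n, n_train = n_train, seed = seed, scan = scan
  ), class = "mode_model")
}

#' @export
print.mode_model <- function(x, ...) {
  cat("Hybrid migration-mode model\n")
  cat("  segments:", x$n, " clusters (k):", x$k, "\n")
  cat("  modes:", paste(x$mode_map, collapse = ", "), "\n")
  cat(sprintf("  held-out agreement with pseudo-labels: %.4f (train %.4f)\n",
              x$heldout_agreement, x$train_agreement))
  cat("  feature importance (gain):\n")
  print(round(x$importance, 4))
  invisible(x)
}

#' Predict migration modes for new segments
#'
#' Applies the model's stored feature scaling and boosted classifier to
#' new per-segment features.
#'
#' @param object A [fit_modes()] model.
#' @param features Tibble with the five feature columns.
#' @param type `"mode"` (named modes) or `"cluster"` (integer cluster).
#' @param ... Unused.
#' @return Character vector of modes, or integer cluster labels.
#' @export
predict.mode_model <- function(object, features,
                               type = c("mode", "cluster"), ...) {
  type <- match.arg(type)
  x <- as.matrix(features[object$feature_names])
  xs <- scale(x, center = object$center, scale = object$scale)
  cl <- predict(object$booster, xgboost::xgb.DMatrix(xs)) + 1
  if (type == "cluster") return(as.integer(cl))
  unname(object$mode_map[as.character(cl)])
}

#' Annotate a trajectory with per-window migration modes
#'
#' Segments preprocessed (gap-free) trajectories into classification
#' windows, computes the five features, and predicts each window's mode
#' with the trained model. Windows failing the admissibility rules are
#' omitted; a trajectory with no valid window yields no rows.
#'
#' @param model A [fit_modes()] model.
#' @param tracks A gap-free track table.
#' @param window Window length in minutes (default 60).
#' @param min_points Minimum samples per window (default 50).
#' @return A mode-sequence tibble of class `"mode_sequence"`:
#'   `track_id`, `window_start_min`, `window_end_min`, `mode`.
#' @export
annotate_modes <- function(model, tracks, window = 60, min_points = 50) {
  segs <- segment_tracks(tracks, window = window, min_points = min_points)
  if (nrow(segs) == 0) {
    out <- tibble::tibble(track_id = character(), window_start_min = numeric(),
                          window_end_min = numeric(), mode = character())
    class(out) <- c("mode_sequence", class(out))
    return(out)
  }
  feats <- track_features(segs)
  out <- feats |>
    dplyr::transmute(.data$track_id, .data$window_start_min,
                     .data$window_end_min,
                     mode = predict(model, feats)) |>
    dplyr::arrange(.data$track_id, .data$window_start_min)
  class(out) <- c("mode_sequence", class(out))
  out
}

#' @describeIn fit_modes Tidy per-cluster summary: one row per cluster
#'   with its mode name and center in original feature units.
#' @param x,object A `mode_model`.
#' @param ... Unused.
#' @export
tidy.mode_model <- function(x, ...) {
  centers <- sweep(sweep(x$centers_scaled, 2, x$scale, "*"), 2, x$center, "+")
  tibble::tibble(cluster = seq_len(x$k),
                 mode = unname(x$mode_map[as.character(seq_len(x$k))]),
                 n_segments = as.integer(table(factor(x$pseudo_labels,
                                                      seq_len(x$k))))) |>
    dplyr::bind_cols(tibble::as_tibble(centers))
}

#' @describeIn fit_modes One-row model summary (k, sizes, agreement,
#'   chosen hyperparameters).
#' @export
glance.mode_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_segments = x$n, n_train = x$n_train,
                 heldout_agreement = x$heldout_agreement,
                 train_agreement = x$train_agreement,
                 max_depth = x$params$max_depth, eta = x$params$eta,
                 nrounds = x$params$nrounds)
}
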