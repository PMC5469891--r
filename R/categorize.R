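## Baseline standardization, polynomial-kernel SVM categorization in one
## and two dimensions, categorization accuracy, decision maps, and exact
## rank-sum comparisons.

#' Standardize features by a per-subject baseline
#'
#' Subtracts, per subject and per feature, the median of that subject's
#' baseline rows (typically the first resting period), so each subject's
#' baseline maps to the origin and subjects become comparable despite
#' different individual levels.  Applying the transform twice is a no-op
#' beyond the first application.
#'
#' @param features A data frame of per-window features with a label column.
#' @param baseline_label Label of the baseline scenario.
#' @param feature_cols Character vector of feature columns to standardize.
#' @param label_col,subject_col Names of the label and subject columns; when
#'   `subject_col` is absent from the data all rows are treated as one
#'   subject.
#' @return A tibble with the same shape, features shifted.
#' @export
standardize_by_baseline <- function(features, baseline_label,
                                    feature_cols = c("LFiA_ms", "HFiA_ms"),
                                    label_col = "label",
                                    subject_col = "subject_id") {
  features <- as_tibble(features)
  if (!label_col %in% names(features))
    abort(sprintf("no `%s` column", label_col))
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols))
    abort(paste("missing feature columns:",
                paste(missing_cols, collapse = ", ")))
  if (!subject_col %in% names(features)) {
    features[[subject_col]] <- "all"
    drop_subject <- TRUE
  } else drop_subject <- FALSE
  labels <- features[[label_col]]
  if (!baseline_label %in% labels)
    abort(sprintf("baseline label '%s' not present", baseline_label))
  out <- features |>
    dplyr::group_by(.data[[subject_col]]) |>
    dplyr::group_modify(function(df, key) {
      base <- df[df[[label_col]] == baseline_label, , drop = FALSE]
      if (nrow(base) == 0)
        abort(sprintf("subject '%s' has no '%s' rows",
                      key[[1]], baseline_label))
      for (f in feature_cols)
        df[[f]] <- df[[f]] - median(base[[f]], na.rm = TRUE)
      df
    }) |>
    dplyr::ungroup()
  if (drop_subject) out[[subject_col]] <- NULL
  out[names(features)[names(features) %in% names(out)]] |>
    (\(x) dplyr::relocate(x, dplyr::any_of(names(features))))()
}

new_categorizer <- function(fit, scaler, features, mode, constant, data,
                            label_col, degree, cost) {
  structure(list(fit = fit, scaler = scaler, features = features,
                 mode = mode, constant = constant, training = data,
                 label_col = label_col, degree = degree, cost = cost),
            class = "hrv_categorizer")
}

scale_features <- function(data, features, scaler) {
  x <- as.matrix(data[features])
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

fit_svm <- function(data, features, label_col, degree, cost, mode,
                    constant_feature = NULL) {
  labels <- factor(data[[label_col]])
  if (nlevels(labels) < 2) abort("need at least 2 classes to fit")
  if (any(table(labels) < 3)) abort("each class needs at least 3 rows")
  x <- as.matrix(data[features])
  if (any(!is.finite(x))) abort("features must be finite")
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  scaler <- list(center = center, scale = scl)
  xs <- scale_features(data, features, scaler)
  if (!is.null(constant_feature)) {
    # 1D mode: the second SVM input is pinned to a constant after scaling
    xs[, constant_feature] <- 0
    scaler$center[constant_feature] <- 0
    scaler$scale[constant_feature] <- 1
  }
  # coef0 = 1 gives the inhomogeneous kernel (1 + gamma u.v)^degree, which
  # spans all monomials up to `degree`; the homogeneous default cannot
  # represent interaction-only boundaries
  fit <- e1071::svm(xs, labels, kernel = "polynomial", degree = degree,
                    cost = cost, coef0 = 1, scale = FALSE)
  new_categorizer(fit, scaler, features, mode,
                  constant = constant_feature, data = data,
                  label_col = label_col, degree = degree, cost = cost)
}

#' Fit a two-dimensional LF-HF categorizer
#'
#' Trains a polynomial-kernel support vector machine on two features
#' (typically the LF and HF instantaneous amplitudes), after per-feature
#' z-scaling.  One-vs-one voting handles more than two classes, and the
#' fitted decision function assigns a stress category to every point of
#' the 2D plane.
#'
#' @param features A data frame of labeled per-window features.
#' @param feature_x,feature_y Names of the two feature columns.
#' @param label_col Name of the label column.
#' @param degree Polynomial kernel degree.
#' @param cost Regularization parameter C.
#' @return An object of class `hrv_categorizer` with [predict()],
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_categorizer_2d <- function(features, feature_x = "LFiA_ms",
                               feature_y = "HFiA_ms", label_col = "label",
                               degree = 3, cost = 1) {
  features <- dplyr::filter(as_tibble(features), !is.na(.data[[label_col]]))
  fit_svm(features, c(feature_x, feature_y), label_col, degree, cost,
          mode = "2d")
}

#' Fit a one-dimensional categorizer through the same pipeline
#'
#' Identical to [fit_categorizer_2d()] except that the second SVM input is
#' replaced by a constant before fitting, so the machine can only exploit
#' one feature; this is how univariate metrics are scored on an equal
#' footing with the 2D representation.  The constant's value is irrelevant
#' to the decision rule and is pinned to 0 (after scaling) for
#' determinism.
#'
#' @inheritParams fit_categorizer_2d
#' @param feature Name of the single feature column to use.
#' @return An `hrv_categorizer`.
#' @export
fit_categorizer_1d <- function(features, feature, label_col = "label",
                               degree = 3, cost = 1) {
  features <- dplyr::filter(as_tibble(features), !is.na(.data[[label_col]]))
  features[[".const"]] <- 0
  fit_svm(features, c(feature, ".const"), label_col, degree, cost,
          mode = "1d", constant_feature = ".const")
}

#' @export
predict.hrv_categorizer <- function(object, newdata = NULL, ...) {
  newdata <- if (is.null(newdata)) object$training else as_tibble(newdata)
  if (object$mode == "1d" && !".const" %in% names(newdata))
    newdata[[".const"]] <- 0
  xs <- scale_features(newdata, object$features, object$scaler)
  if (!is.null(object$constant)) xs[, object$constant] <- 0
  predict(object$fit, xs)
}

#' @export
print.hrv_categorizer <- function(x, ...) {
  cat(sprintf(
    "<hrv_categorizer> %s, polynomial kernel (degree %d, C = %g)\n",
    if (x$mode == "2d") paste(x$features, collapse = " x ") else x$features[1],
    x$degree, x$cost))
  cat(sprintf("  classes: %s; %d training rows, %d support vectors\n",
              paste(x$fit$levels, collapse = ", "), nrow(x$training),
              x$fit$tot.nSV))
  invisible(x)
}

#' Categorization accuracy
#'
#' Percentage of windows assigned to the correct scenario label.  The
#' default is resubstitution accuracy on the training windows (how
#' separable the scenarios are in the chosen representation); k-fold
#' cross-validation is available for a stricter generalization estimate.
#'
#' @param model An `hrv_categorizer`.
#' @param features Data to score; defaults to the model's training data.
#' @param mode `"resubstitution"` or `"cv"`.
#' @param folds Number of folds for `mode = "cv"`.
#' @param seed Seed for the fold assignment.
#' @return Accuracy in percent (0--100).
#' @export
categorization_accuracy <- function(model, features = NULL,
                                    mode = c("resubstitution", "cv"),
                                    folds = 5, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "hrv_categorizer"))
  features <- if (is.null(features)) model$training else as_tibble(features)
  if (nrow(features) == 0) abort("no rows to score")
  truth <- factor(features[[model$label_col]])
  if (mode == "resubstitution") {
    pred <- predict(model, features)
    return(100 * mean(as.character(pred) == as.character(truth)))
  }
  with_local_seed(seed, {
    fold <- sample(rep_len(seq_len(folds), nrow(features)))
    correct <- logical(nrow(features))
    for (f in seq_len(folds)) {
      train <- features[fold != f, , drop = FALSE]
      test <- features[fold == f, , drop = FALSE]
      m <- if (model$mode == "2d") {
        fit_categorizer_2d(train, model$features[1], model$features[2],
                           model$label_col, model$degree, model$cost)
      } else {
        fit_categorizer_1d(train, model$features[1], model$label_col,
                           model$degree, model$cost)
      }
      correct[fold == f] <-
        as.character(predict(m, test)) == as.character(truth[fold == f])
    }
    100 * mean(correct)
  })
}

#' Confusion counts of a categorizer
#'
#' @param model An `hrv_categorizer`.
#' @param features Data to score; defaults to the training data.
#' @return A tibble with columns `truth`, `prediction`, `n`.
#' @export
confusion_counts <- function(model, features = NULL) {
  features <- if (is.null(features)) model$training else as_tibble(features)
  pred <- predict(model, features)
  as_tibble(as.data.frame(table(
    truth = factor(features[[model$label_col]]),
    prediction = pred), responseName = "n"))
}

#' Rasterize the decision regions of a categorizer
#'
#' Evaluates the fitted decision function on a regular grid of the 2D
#' feature plane, yielding the label raster used as the background of
#' LF-HF scatter plots.
#'
#' @param model An `hrv_categorizer`.
#' @param xlim,ylim Plane bounds; default to the training range expanded
#'   by 10%.
#' @param resolution Number of grid cells per axis.
#' @return A tibble with columns `x`, `y`, `label`.
#' @export
decision_map <- function(model, xlim = NULL, ylim = NULL, resolution = 200) {
  stopifnot(inherits(model, "hrv_categorizer"))
  if (resolution <= 0) abort("`resolution` must be positive")
  pad <- function(r) r + c(-1, 1) * 0.1 * diff(r)
  xlim <- xlim %||% pad(range(model$training[[model$features[1]]]))
  ylim <- ylim %||% pad(range(model$training[[if (model$mode == "2d")
    model$features[2] else ".const"]]))
  if (!all(is.finite(c(xlim, ylim)))) abort("bounds must be finite")
  if (model$mode == "1d") ylim <- c(-1, 1)
  grid <- tidyr::expand_grid(x = seq(xlim[1], xlim[2], length.out = resolution),
                             y = seq(ylim[1], ylim[2], length.out = resolution))
  nd <- tibble(!!model$features[1] := grid$x)
  if (model$mode == "2d") nd[[model$features[2]]] <- grid$y
  else nd[[".const"]] <- 0
  grid$label <- predict(model, nd)
  grid
}

#' @importFrom rlang :=
NULL

#' Exact rank-sum comparison of two scenarios
#'
#' Two-sided Wilcoxon rank-sum test on one aggregate value per subject and
#' scenario.  For small untied samples the p-value is exact (enumeration
#' over all rank assignments); fully separated groups of 5 vs 5 give
#' p = 2/252.
#'
#' @param values_a,values_b Per-subject aggregate values for the two
#'   scenarios.
#' @return The two-sided p-value.
#' @export
wilcoxon_scenarios <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    abort("both groups must be non-empty")
  suppressWarnings(
    wilcox.test(values_a, values_b, exact = TRUE, correct = FALSE)$p.value)
}

#' @method tidy hrv_categorizer
#' @export
tidy.hrv_categorizer <- function(x, ...) {
  cc <- confusion_counts(x)
  dplyr::mutate(cc, correct = as.character(.data$truth) ==
                  as.character(.data$prediction))
}

#' @method glance hrv_categorizer
#' @export
glance.hrv_categorizer <- function(x, ...) {
  tibble(mode = x$mode,
         features = paste(setdiff(x$features, ".const"), collapse = ":"),
         degree = x$degree, cost = x$cost,
         n = nrow(x$training),
         n_classes = length(x$fit$levels),
         n_support = x$fit$tot.nSV,
         accuracy_pct = categorization_accuracy(x))
}
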