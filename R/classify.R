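# Cross-validated phenotype classification: repeated stratified k-fold CV of
# a small feed-forward network (or a logistic-regression fallback) over
# exhaustively enumerated predictor subsets; per-parameter importance as the
# mean CV accuracy of all models containing the parameter; top-k curves and
# the one-SEM minimal-model rule; confusion-matrix evaluation with half-up
# integer-percent rounding.

#' Classifier configuration
#'
#' Declares the classification model and cross-validation protocol. The
#' default family is a single-hidden-layer feed-forward network with a small
#' fixed hyperparameter grid (hidden units x weight decay), selected by the
#' same repeated CV; `"logistic"` is a fast logistic-regression fallback
#' with no grid. Inputs are standardized inside each training fold.
#'
#' @param model_family `"nnet"` or `"logistic"`.
#' @param hidden_units Integer grid of hidden-layer sizes (nnet only).
#' @param decay Numeric grid of weight-decay strengths (nnet only).
#' @param cv_folds Folds per CV repeat (>= 2; default 5).
#' @param cv_repeats CV repeats (default 10); the SEM of accuracy is taken
#'   across repeat-level accuracies.
#' @param seed Integer seed controlling folds and model initialization.
#' @param standardize Standardize features within training folds
#'   (default TRUE).
#' @param maxit Training iterations for the network.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(model_family = c("nnet", "logistic"),
                              hidden_units = c(4L, 8L, 16L),
                              decay = c(0.01, 0.1),
                              cv_folds = 5L, cv_repeats = 10L, seed = 1L,
                              standardize = TRUE, maxit = 200L) {
  model_family <- match.arg(model_family)
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.")
  if (cv_repeats < 1) abort("`cv_repeats` must be >= 1.")
  structure(
    list(model_family = model_family,
         hidden_units = as.integer(hidden_units), decay = as.numeric(decay),
         cv_folds = as.integer(cv_folds), cv_repeats = as.integer(cv_repeats),
         seed = as.integer(seed), standardize = isTRUE(standardize),
         maxit = as.integer(maxit)),
    class = "classifier_config"
  )
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin into folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
  }
  fold
}

fit_predict <- function(xtr, ytr, xte, family, size, decay, maxit) {
  if (family == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, xtr), ytr, family = stats::binomial())
    )
    eta <- cbind(1, xte) %*% fit$coefficients
    as.integer(eta > 0)
  } else {
    fit <- nnet::nnet(xtr, ytr, size = size, decay = decay, maxit = maxit,
                      entropy = TRUE, trace = FALSE)
    as.integer(stats::predict(fit, xte) > 0.5)
  }
}

#' Repeated cross-validation of one predictor subset
#'
#' Trains the configured classifier on the given descriptor subset with
#' repeated stratified k-fold cross-validation and returns the mean held-out
#' accuracy with its SEM over repeats. For the network family, every grid
#' point (hidden units x decay) is evaluated on the same folds and the best
#' grid point's result is reported. Fully reproducible from `config$seed`;
#' the subset is used in canonical (alphabetical) column order so equal sets
#' give identical results.
#'
#' @param records Morphology record tibble with a two-level `phenotype`
#'   column and the descriptor columns.
#' @param subset Character vector of descriptor names (length >= 1).
#' @param config A [classifier_config()].
#' @param return_predictions If `TRUE`, attach pooled out-of-fold
#'   predictions from the first CV repeat (attribute `"predictions"`).
#' @return A `subset_result` list: `subset`, `mean_accuracy`,
#'   `sem_accuracy`, `per_repeat_accuracies`, `per_fold_accuracies`,
#'   `best_config`.
#' @export
train_cv <- function(records, subset, config = classifier_config(),
                     return_predictions = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  if (length(subset) < 1) abort("`subset` must contain at least one parameter.")
  missing_p <- setdiff(subset, names(records))
  if (length(missing_p)) {
    abort(sprintf("unknown parameter(s): %s.", paste(missing_p, collapse = ", ")))
  }
  subset <- sort(unique(subset))
  y <- factor(records$phenotype)
  if (nlevels(y) < 2) abort("records contain a single class.",
                            class = "colonymorph_single_class")
  X <- as.matrix(records[, subset, drop = FALSE])
  storage.mode(X) <- "double"
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- droplevels(y[keep])
  if (nlevels(y) < 2) abort("records contain a single class after filtering.",
                            class = "colonymorph_single_class")
  y01 <- as.integer(y) - 1L
  grid <- if (config$model_family == "logistic") {
    data.frame(size = NA_integer_, decay = NA_real_)
  } else {
    expand.grid(size = config$hidden_units, decay = config$decay,
                KEEP.OUT.ATTRS = FALSE)
  }
  R <- config$cv_repeats; K <- config$cv_folds
  acc <- array(NA_real_, c(nrow(grid), R, K))
  preds_first <- matrix(NA_integer_, nrow(grid), length(y01))
  with_seed(config$seed, {
    for (r in seq_len(R)) {
      fold <- stratified_folds(y, K)
      for (k in seq_len(K)) {
        te <- fold == k
        xtr <- X[!te, , drop = FALSE]; xte <- X[te, , drop = FALSE]
        if (config$standardize) {
          mu <- colMeans(xtr)
          sdv <- apply(xtr, 2, stats::sd)
          sdv[sdv == 0] <- 1
          xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
          xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
        }
        for (g in seq_len(nrow(grid))) {
          p <- fit_predict(xtr, y01[!te], xte, config$model_family,
                           grid$size[g], grid$decay[g], config$maxit)
          acc[g, r, k] <- mean(p == y01[te])
          if (r == 1L) preds_first[g, te] <- p
        }
      }
    }
  })
  rep_acc <- apply(acc, c(1, 2), mean)           # grid x repeat
  mean_acc <- rowMeans(rep_acc)
  best <- which.max(mean_acc)
  sem <- if (R > 1) stats::sd(rep_acc[best, ]) / sqrt(R) else 0
  res <- structure(
    list(subset = subset,
         mean_accuracy = mean_acc[best],
         sem_accuracy = sem,
         per_repeat_accuracies = rep_acc[best, ],
         per_fold_accuracies = acc[best, , ],
         best_config = list(model_family = config$model_family,
                            size = grid$size[best], decay = grid$decay[best]),
         n = length(y01)),
    class = "subset_result"
  )
  if (return_predictions) {
    attr(res, "predictions") <- factor(levels(y)[preds_first[best, ] + 1L],
                                       levels = levels(y))
    attr(res, "observed") <- y
  }
  res
}

#' @export
print.subset_result <- function(x, ...) {
  cat(sprintf("<subset_result> {%s}: accuracy %.3f +/- %.3f (n = %d)\n",
              paste(x$subset, collapse = ", "), x$mean_accuracy,
              x$sem_accuracy, x$n))
  invisible(x)
}

#' Enumerate predictor subsets
#'
#' All subsets of the parameter list with sizes in `[min_size, max_size]`,
#' in deterministic order (by size, then combination order).
#'
#' @param parameters Character vector of parameter names.
#' @param min_size,max_size Size range (defaults 2 and all parameters).
#' @return List of character vectors.
#' @export
enumerate_subsets <- function(parameters, min_size = 2L,
                              max_size = length(parameters)) {
  if (!length(parameters)) abort("`parameters` must not be empty.")
  if (min_size > max_size) abort("`min_size` must be <= `max_size`.")
  if (min_size < 1) abort("`min_size` must be >= 1.")
  out <- list()
  for (s in seq(min_size, min(max_size, length(parameters)))) {
    combos <- utils::combn(parameters, s, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Per-parameter importance from exhaustive subset training
#'
#' Trains the classifier on every subset of the parameters (sizes 2 up to
#' all) and scores each parameter by the unweighted mean of the mean CV
#' accuracies of all subsets containing it: a higher value means the
#' parameter's presence in a model, on average, yields higher phenotype
#' prediction accuracy. Ties are broken alphabetically.
#'
#' @inheritParams train_cv
#' @param parameters Character vector of descriptor names to enumerate.
#' @return Tibble (`parameter`, `importance`, `n_models`) sorted by
#'   descending importance, with the per-subset results in attribute
#'   `"subset_results"`.
#' @export
importance_table <- function(records, parameters = NULL,
                             config = classifier_config()) {
  if (is.null(parameters)) {
    parameters <- intersect(descriptor_names("colony"), names(records))
  }
  subsets <- enumerate_subsets(parameters, min_size = 2L)
  results <- lapply(subsets, function(s) {
    tryCatch(train_cv(records, s, config),
             error = function(e) {
               abort(sprintf("training failed for subset {%s}: %s",
                             paste(s, collapse = ", "), conditionMessage(e)),
                     parent = e)
             })
  })
  accs <- vapply(results, function(r) r$mean_accuracy, numeric(1))
  imp <- vapply(parameters, function(p) {
    mean(accs[vapply(subsets, function(s) p %in% s, logical(1))])
  }, numeric(1))
  nmod <- vapply(parameters, function(p) {
    sum(vapply(subsets, function(s) p %in% s, logical(1)))
  }, integer(1))
  out <- tibble(parameter = parameters, importance = unname(imp),
                n_models = unname(nmod))
  out <- out[order(-out$importance, out$parameter), ]
  attr(out, "subset_results") <- results
  class(out) <- c("importance_table", class(out))
  out
}

#' Accuracy versus number of best parameters
#'
#' For k = 2 up to the number of parameters, trains the model on the k most
#' important parameters (descending importance order) and returns the
#' accuracy-vs-k curve.
#'
#' @inheritParams train_cv
#' @param importance An [importance_table()] computed on the same parameters.
#' @return Tibble: `k`, `subset` (comma-joined), `mean_accuracy`,
#'   `sem_accuracy`.
#' @export
topk_curve <- function(records, importance, config = classifier_config()) {
  stopifnot(inherits(importance, "importance_table"))
  ranked <- importance$parameter
  p <- length(ranked)
  rows <- lapply(2:p, function(k) {
    s <- ranked[seq_len(k)]
    r <- train_cv(records, s, config)
    tibble(k = k, subset = paste(sort(s), collapse = ","),
           mean_accuracy = r$mean_accuracy, sem_accuracy = r$sem_accuracy)
  })
  dplyr::bind_rows(rows)
}

#' Minimal-model selection (one-SEM rule)
#'
#' Picks the smallest k whose mean CV accuracy is within one SEM (the SEM at
#' the maximizer) of the best accuracy on the curve: the smallest model
#' statistically indistinguishable from the best, since adding further
#' parameters does not improve performance.
#'
#' @param curve Tibble as returned by [topk_curve()] (columns `k`,
#'   `mean_accuracy`, `sem_accuracy`, optionally `subset`).
#' @return List: `k`, `subset` (or `NULL` if the curve has no subset
#'   column), `threshold`, `max_accuracy`.
#' @export
select_minimal_model <- function(curve) {
  if (!nrow(curve)) abort("`curve` is empty.")
  i_max <- which.max(curve$mean_accuracy)
  thr <- curve$mean_accuracy[i_max] - curve$sem_accuracy[i_max]
  ok <- which(curve$mean_accuracy >= thr)
  i_star <- ok[which.min(curve$k[ok])]
  list(k = curve$k[i_star],
       subset = if ("subset" %in% names(curve)) {
         strsplit(curve$subset[i_star], ",")[[1]]
       } else NULL,
       threshold = thr,
       max_accuracy = curve$mean_accuracy[i_max])
}

#' Confusion matrix from aligned labels
#'
#' @param observed,predicted Vectors of class labels (coerced to a common
#'   factor; for phenotype data the class order is `bad`, `good`).
#' @return 2x2 (or c x c) integer matrix, observed in rows, predicted in
#'   columns.
#' @export
confusion_matrix <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.")
  }
  levs <- sort(unique(c(as.character(observed), as.character(predicted))))
  o <- factor(as.character(observed), levels = levs)
  p <- factor(as.character(predicted), levels = levs)
  if (anyNA(o) || anyNA(p)) abort("labels contain missing values.")
  tab <- table(observed = o, predicted = p)
  m <- matrix(as.integer(tab), nrow = nlevels(o),
              dimnames = list(observed = levs, predicted = levs))
  m
}

#' Build a 2x2 confusion matrix from printed counts
#'
#' @param bad_bad Bad observed, predicted bad (correct).
#' @param bad_good Bad observed, predicted good.
#' @param good_bad Good observed, predicted bad.
#' @param good_good Good observed, predicted good (correct).
#' @return 2x2 integer matrix (rows observed, columns predicted).
#' @export
confusion_from_counts <- function(bad_bad, bad_good, good_bad, good_good) {
  m <- matrix(as.integer(c(bad_bad, good_bad, bad_good, good_good)), 2L, 2L,
              dimnames = list(observed = c("bad", "good"),
                              predicted = c("bad", "good")))
  if (any(m < 0)) abort("counts must be non-negative.")
  m
}

#' Confusion-matrix metrics
#'
#' Overall accuracy (trace over total) and the per-class rate of correct
#' classification: correctly classified members of an observed class divided
#' by that class's observed total (the class recall, often reported in
#' published confusion tables as per-class precision). Percentages are
#' rounded half-up to integers, the convention of such tables.
#'
#' @param cm Confusion matrix (observed x predicted), e.g. from
#'   [confusion_matrix()] or [confusion_from_counts()].
#' @return List: `accuracy`, `per_class` (named fractions), `accuracy_pct`,
#'   `per_class_pct` (half-up integer percents), `n`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) abort("confusion matrix must be square.")
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  per <- diag(cm) / rowSums(cm)
  list(accuracy = acc, per_class = per,
       accuracy_pct = round_half_up(100 * acc),
       per_class_pct = round_half_up(100 * per),
       n = n)
}

#' Evaluate predictions against observed labels
#'
#' Confusion matrix plus metrics, with per-line misclassification counts
#' when line metadata is supplied.
#'
#' @param observed,predicted Aligned label vectors.
#' @param line Optional vector of line labels, aligned with `observed`.
#' @return List: `confusion`, `metrics`, and `per_line` (tibble of
#'   misclassification counts per line, or `NULL`).
#' @export
evaluate_predictions <- function(observed, predicted, line = NULL) {
  cm <- confusion_matrix(observed, predicted)
  out <- list(confusion = cm, metrics = confusion_metrics(cm),
              per_line = NULL)
  if (!is.null(line)) {
    if (length(line) != length(observed)) {
      abort("`line` must be aligned with `observed`.")
    }
    wrong <- as.character(observed) != as.character(predicted)
    out$per_line <- dplyr::summarise(
      dplyr::group_by(tibble(line = line, wrong = wrong), .data$line),
      n = dplyr::n(), misclassified = sum(.data$wrong),
      misclassified_pct = round_half_up(100 * sum(.data$wrong) / dplyr::n()),
      .groups = "drop"
    )
  }
  out
}

#' Per-line classification models
#'
#' Trains the same CV protocol separately within each line. Lines with a
#' single phenotype class are skipped with a warning.
#'
#' @inheritParams train_cv
#' @param parameters Descriptor subset used for every line.
#' @return Named list of `subset_result` objects, one per usable line.
#' @export
per_line_models <- function(records, parameters,
                            config = classifier_config()) {
  out <- list()
  for (ln in sort(unique(records$line))) {
    sub <- records[records$line == ln, ]
    if (length(unique(sub$phenotype[!is.na(sub$phenotype)])) < 2) {
      warn(sprintf("line %s has a single phenotype class; skipped.", ln))
      next
    }
    out[[ln]] <- train_cv(sub, parameters, config)
  }
  out
}

#' Drop near-collinear parameters
#'
#' Greedy pre-filter reproducing the preliminary exclusion of redundant
#' descriptors: walking the parameter list in order, a parameter is dropped
#' when its absolute Pearson correlation with an already-retained parameter
#' exceeds the threshold.
#'
#' @param records Morphology record tibble.
#' @param parameters Parameters to screen, in priority order.
#' @param threshold Absolute correlation above which a parameter is dropped
#'   (default 0.95).
#' @return Character vector of retained parameters, with the dropped ones in
#'   attribute `"dropped"`.
#' @export
drop_correlated <- function(records, parameters, threshold = 0.95) {
  X <- as.matrix(records[, parameters, drop = FALSE])
  keep <- character(0); dropped <- character(0)
  for (p in parameters) {
    if (!length(keep)) { keep <- p; next }
    r <- suppressWarnings(
      abs(stats::cor(X[, p], X[, keep, drop = FALSE],
                     use = "pairwise.complete.obs"))
    )
    if (any(r > threshold, na.rm = TRUE)) dropped <- c(dropped, p)
    else keep <- c(keep, p)
  }
  structure(keep, dropped = dropped)
}
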