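# Two-layer predictor: grid-search optimization layer and RBF-kernel
# soft-margin classification layer with sigmoid-calibrated probabilities.
# The kernel machine itself is fitted through e1071 (libsvm); everything
# around it — subset draw, stratified folds, balanced-accuracy scoring,
# oversampling, Platt calibration — is seeded R code so that identical
# (inputs, hyperparameters, seed) give byte-identical predictions.

# Run `expr` under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Hyperparameter set for the disorder classifier
#'
#' Defaults are the optimized window-21 settings: cost 2, RBF gamma
#' 0.0078125 (both powers of two found by the grid search), window size 21,
#' decision threshold 0.5 and 2x oversampling of disorder rows during
#' training.
#'
#' @param cost Positive misclassification cost C.
#' @param gamma Positive RBF width parameter.
#' @param window Odd sliding-window size.
#' @param threshold Decision cutoff in (0,1); probability >= threshold is
#'   called disorder.
#' @param oversample Integer >= 1; total copies of each disorder-labelled
#'   training row.
#' @return List of class \code{hyper_params}.
#' @export
hyper_params <- function(cost = 2, gamma = 0.0078125, window = 21L,
                         threshold = 0.5, oversample = 2L) {
  stopifnot(cost > 0, gamma > 0, threshold > 0, threshold < 1)
  if (window < 1 || window %% 2 == 0)
    stop("window size must be odd and >= 1, got ", window)
  if (oversample < 1) stop("oversample factor must be >= 1")
  structure(list(cost = cost, gamma = gamma, window = as.integer(window),
                 threshold = threshold, oversample = as.integer(oversample)),
            class = "hyper_params")
}

#' Oversample disorder-labelled rows
#'
#' Duplicates every disorder row so it appears \code{factor} times in total;
#' order rows are untouched.  Applied to training folds only — evaluation
#' always runs on the un-duplicated residue set.
#'
#' @param x Feature matrix.
#' @param labels Per-row labels (\code{"D"}/\code{"O"}).
#' @param factor Integer >= 1.
#' @return List with the expanded \code{x} and \code{labels}.
#' @export
oversample_minority <- function(x, labels, factor = 2L) {
  if (factor < 1) stop("oversample factor must be >= 1")
  stopifnot(nrow(x) == length(labels))
  if (factor == 1L) return(list(x = x, labels = labels))
  extra <- rep(which(labels == "D"), factor - 1L)
  idx <- c(seq_along(labels), extra)
  list(x = x[idx, , drop = FALSE], labels = labels[idx])
}

# Stratified k-fold assignment: within each class, units are assigned
# round-robin in a seeded random order.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      fold[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
    }
  })
  fold
}

# Fit one RBF SVM and return a function mapping rows to decision values
# with positive = disorder.
fit_rbf <- function(x, y, cost, gamma) {
  yf <- factor(y, levels = c("O", "D"))
  if (length(unique(y)) < 2L)
    stop("training set contains a single class")
  m <- e1071::svm(x, yf, type = "C-classification", kernel = "radial",
                  cost = cost, gamma = gamma, scale = FALSE,
                  cachesize = 256)
  decide <- function(newx) {
    dv <- attr(stats::predict(m, newx, decision.values = TRUE),
               "decision.values")
    # libsvm's sign convention depends on class order seen in training
    if (grepl("^O/", colnames(dv)[1])) -dv[, 1] else dv[, 1]
  }
  list(svm = m, decide = decide)
}

#' Grid search for (cost, gamma)
#'
#' Draws a seeded uniform random subset of the labelled training rows
#' (default 5\%) and evaluates a powers-of-two grid — C over 2^-5..2^15 and
#' gamma over 2^-15..2^3, both in steps of 2^2 — by stratified k-fold
#' cross-validated balanced accuracy on that subset.  Ties are broken
#' towards the smallest cost, then the smallest gamma (the smoother model).
#'
#' @param x Scaled feature matrix (training rows only).
#' @param labels Per-row labels (\code{"D"}/\code{"O"}); no unknowns.
#' @param subset_fraction Fraction of rows used for the search (0, 1].
#' @param seed Integer seed (mandatory, recorded in the result).
#' @param k Folds for the internal cross-validation (default 5).
#' @param cost_grid,gamma_grid Candidate values; defaults as above.
#' @return List of class \code{grid_search_result}: \code{best} (named
#'   vector with cost and gamma), \code{grid} (data frame of cost, gamma,
#'   cv score), \code{subset_fraction}, \code{seed}.
#' @export
grid_search <- function(x, labels, subset_fraction = 0.05, seed,
                        k = 5L,
                        cost_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2)) {
  stopifnot(subset_fraction > 0, subset_fraction <= 1)
  if (missing(seed)) stop("a seed is mandatory for grid_search")
  n <- nrow(x)
  idx <- with_seed(seed, sort(sample.int(n, max(2L, round(n * subset_fraction)))))
  xs <- x[idx, , drop = FALSE]
  ys <- labels[idx]
  if (min(table(factor(ys, levels = c("O", "D")))) < k)
    stop("subset too small to stratify ", k,
         " folds; increase subset_fraction")
  fold <- stratified_folds(ys, k, seed + 1L)
  combos <- expand.grid(gamma = gamma_grid, cost = cost_grid)
  score <- vapply(seq_len(nrow(combos)), function(ci) {
    accs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- fit_rbf(xs[tr, , drop = FALSE], ys[tr],
                     combos$cost[ci], combos$gamma[ci])
      pred <- ifelse(fit$decide(xs[!tr, , drop = FALSE]) >= 0, "D", "O")
      truth <- ys[!tr]
      sens <- mean(pred[truth == "D"] == "D")
      spec <- mean(pred[truth == "O"] == "O")
      (sens + spec) / 2
    }, 0)
    mean(accs)
  }, 0)
  grid <- data.frame(cost = combos$cost, gamma = combos$gamma, score = score)
  ord <- order(-grid$score, grid$cost, grid$gamma)
  best <- grid[ord[1L], ]
  structure(list(best = c(cost = best$cost, gamma = best$gamma),
                 grid = grid, subset_fraction = subset_fraction,
                 seed = seed),
            class = "grid_search_result")
}

# Platt sigmoid fit: p(D | f) = 1 / (1 + exp(A f + B)), coefficients found
# by minimizing the calibration log-loss with Platt's smoothed targets.
platt_fit <- function(dv, y) {
  np <- sum(y == "D"); nn <- sum(y == "O")
  t <- ifelse(y == "D", (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(ab) {
    z <- ab[1] * dv + ab[2]
    # stable log(1+exp(z)) and cross-entropy
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  fit <- stats::optim(c(-1, 0), nll, method = "BFGS",
                      control = list(maxit = 200))
  c(A = fit$par[1], B = fit$par[2])
}

platt_prob <- function(coef, dv) {
  1 / (1 + exp(coef["A"] * dv + coef["B"]))
}

#' Train the disorder classifier
#'
#' Fits the full classification layer on labelled windowed features:
#' per-column \[-1,+1\] scaler (training rows only), oversampling of
#' disorder rows, soft-margin RBF SVM with kernel
#' \eqn{k(u,v) = \exp(-\gamma \|u-v\|^2)} and cost C, and a sigmoid
#' probability calibration fitted on decision values from a seeded internal
#' 5-fold cross-validation.  For bounded cost the calibration fold models
#' are trained on a stratified subsample of at most \code{calib_max} rows.
#'
#' @param x Unscaled windowed feature matrix (training rows only, no
#'   unknown labels).
#' @param labels Per-row labels (\code{"D"}/\code{"O"}).
#' @param hp A [hyper_params()] object.
#' @param seed Integer seed (mandatory).
#' @param calib_folds Internal calibration folds (default 5).
#' @param calib_max Row cap for the calibration cross-validation.
#' @return Object of class \code{disorder_model}.
#' @export
train_predictor <- function(x, labels, hp = hyper_params(), seed,
                            calib_folds = 5L, calib_max = 5000L) {
  if (missing(seed)) stop("a seed is mandatory for train_predictor")
  stopifnot(nrow(x) == length(labels), all(labels %in% c("O", "D")))
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  over <- oversample_minority(xs, labels, hp$oversample)
  fit <- fit_rbf(over$x, over$labels, hp$cost, hp$gamma)

  # calibration: held-out decision values from an internal CV on (a
  # stratified subsample of) the same training distribution
  n <- length(over$labels)
  ci <- if (n > calib_max) {
    with_seed(seed + 7L, {
      keep <- unlist(lapply(c("O", "D"), function(cl) {
        i <- which(over$labels == cl)
        sample(i, round(calib_max * length(i) / n))
      }))
      sort(keep)
    })
  } else seq_len(n)
  cx <- over$x[ci, , drop = FALSE]
  cy <- over$labels[ci]
  fold <- stratified_folds(cy, calib_folds, seed + 13L)
  dv <- numeric(length(cy))
  for (f in seq_len(calib_folds)) {
    tr <- fold != f
    cf <- fit_rbf(cx[tr, , drop = FALSE], cy[tr], hp$cost, hp$gamma)
    dv[!tr] <- cf$decide(cx[!tr, , drop = FALSE])
  }
  calib <- platt_fit(dv, cy)

  structure(list(svm = fit$svm, scaler = scaler, hp = hp, calib = calib,
                 seed = seed, format_version = MODEL_FORMAT_VERSION),
            class = "disorder_model")
}

#' @export
print.disorder_model <- function(x, ...) {
  cat(sprintf(paste0("<disorder_model> window=%d cost=%g gamma=%g ",
                     "threshold=%g oversample=%d (%d SVs)\n"),
              x$hp$window, x$hp$cost, x$hp$gamma, x$hp$threshold,
              x$hp$oversample, sum(x$svm$tot.nSV)))
  invisible(x)
}

#' Predict per-residue disorder
#'
#' Applies the model's own scaler, computes RBF decision values, maps them
#' through the fitted sigmoid to disorder probabilities in \[0,1\], and
#' binarizes at the model threshold (probability >= threshold is disorder).
#'
#' @param model A \code{disorder_model}.
#' @param x Unscaled windowed feature matrix.
#' @param meta Optional per-row back-reference data frame (\code{id},
#'   \code{pos}, \code{residue}, ...) as produced by
#'   [featurize_dataset()]; carried through to the result.
#' @param threshold Optional override of the model's decision threshold.
#' @return Data frame with \code{prob} and \code{call} (\code{"D"}/
#'   \code{"O"}) columns, preceded by the \code{meta} columns when given.
#' @export
predict_disorder <- function(model, x, meta = NULL, threshold = NULL) {
  stopifnot(inherits(model, "disorder_model"))
  if (ncol(x) != length(model$scaler$min))
    stop("feature matrix has ", ncol(x), " columns but the model expects ",
         length(model$scaler$min),
         " (window size ", model$hp$window, ")")
  thr <- if (is.null(threshold)) model$hp$threshold else threshold
  xs <- apply_scaler(model$scaler, x)
  dv <- attr(stats::predict(model$svm, xs, decision.values = TRUE),
             "decision.values")
  dv <- if (grepl("^O/", colnames(dv)[1])) -dv[, 1] else dv[, 1]
  prob <- pmin(pmax(platt_prob(model$calib, dv), 0), 1)
  out <- data.frame(prob = unname(prob),
                    call = ifelse(prob >= thr, "D", "O"),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) out <- cbind(meta, out)
  out
}

#' Group a prediction data frame into per-chain records
#'
#' @param pred Data frame from [predict_disorder()] carrying \code{id},
#'   \code{pos} and \code{residue} columns.
#' @return List of per-chain records suitable for [write_predictions()].
#' @export
prediction_records <- function(pred) {
  stopifnot(all(c("id", "residue", "prob", "call") %in% names(pred)))
  lapply(split(pred, factor(pred$id, levels = unique(pred$id))),
         function(b) list(id = b$id[1], residues = b$residue,
                          prob = b$prob, call = b$call))
}
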