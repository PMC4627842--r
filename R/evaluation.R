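# CASP-style assessment: confusion metrics, weighted score Sw, MCC,
# content-level MAE, rank AUC with stratified bootstrap CIs, fold
# construction and the train/test window-overlap probability.

#' Confusion counts for binary disorder prediction
#'
#' Disorder is the positive class: TP = correctly predicted disordered
#' residues, TN = correctly predicted ordered, FP = ordered residues called
#' disordered, FN = disordered residues called ordered.  Unknown-labelled
#' residues must be excluded before calling.
#'
#' @param truth Character vector over \code{c("O","D")}.
#' @param pred Character vector over \code{c("O","D")}, same length.
#' @return List of class \code{confusion_counts} with TP, TN, FP, FN.
#' @export
confusion <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (any(truth == "U") || any(pred == "U"))
    stop("unknown-labelled residues must be excluded before scoring")
  stopifnot(all(truth %in% c("O", "D")), all(pred %in% c("O", "D")))
  structure(list(TP = sum(truth == "D" & pred == "D"),
                 TN = sum(truth == "O" & pred == "O"),
                 FP = sum(truth == "O" & pred == "D"),
                 FN = sum(truth == "D" & pred == "O")),
            class = "confusion_counts")
}

#' Binary prediction metrics
#'
#' Computes the CASP binary assessment suite from confusion counts:
#' sensitivity TP/Nd, specificity TN/No, balanced accuracy
#' ACC = (SENS + SPEC)/2, the prevalence-weighted score
#' \deqn{S_w = (w_d TP - w_o FP + w_o TN - w_d FN) / (w_d N_d + w_o N_o)}
#' with \eqn{w_d = N_o/(N_o+N_d)} and \eqn{w_o = N_d/(N_o+N_d)} (so that
#' \eqn{S_w = 2 ACC - 1}), precision PPV = TP/(TP+FP), and the Matthews
#' correlation coefficient.  Any metric whose denominator is zero is
#' reported as \code{NA} rather than 0.
#'
#' @param counts A \code{confusion_counts} object (or list with TP, TN,
#'   FP, FN).
#' @return List of class \code{metric_report}.
#' @export
binary_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop("negative confusion counts")
  Nd <- TP + FN; No <- TN + FP; N <- Nd + No
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- div(TP, Nd)
  spec <- div(TN, No)
  acc <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  sw <- if (Nd == 0 || No == 0) NA_real_ else {
    wd <- No / N; wo <- Nd / N
    (wd * TP - wo * FP + wo * TN - wd * FN) / (wd * Nd + wo * No)
  }
  ppv <- div(TP, TP + FP)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) NA_real_ else
    (TP * TN - FP * FN) / mcc_den
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 N_d = Nd, N_o = No, N_correct = TP + TN,
                 SENS = sens, SPEC = spec, ACC = acc, Sw = sw,
                 PPV = ppv, MCC = mcc,
                 AUC = NA_real_, AUC_CI = c(NA_real_, NA_real_),
                 MAE = NA_real_),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  f <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d (N=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$N_d + x$N_o))
  cat(sprintf("SENS=%s SPEC=%s ACC=%s Sw=%s PPV=%s MCC=%s\n",
              f(x$SENS), f(x$SPEC), f(x$ACC), f(x$Sw), f(x$PPV), f(x$MCC)))
  if (!is.na(x$AUC))
    cat(sprintf("AUC=%s [%s, %s]\n", f(x$AUC), f(x$AUC_CI[1]),
                f(x$AUC_CI[2])))
  if (!is.na(x$MAE)) cat(sprintf("MAE=%s\n", f(x$MAE)))
  invisible(x)
}

#' Mean absolute error of per-chain disorder content
#'
#' @param actual,predicted Per-chain disorder-content fractions in \[0,1\],
#'   equal length.
#' @return Mean of \code{abs(actual - predicted)}.
#' @export
content_mae <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  if (!length(actual)) stop("empty content vectors")
  stopifnot(all(actual >= 0 & actual <= 1),
            all(predicted >= 0 & predicted <= 1))
  mean(abs(actual - predicted))
}

#' ROC analysis with stratified bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with tie correction; the 95\%
#' confidence interval by a stratified percentile bootstrap (positives and
#' negatives resampled separately).  Also returns ROC and precision-recall
#' curve points over the observed thresholds.
#'
#' @param truth Character vector over \code{c("O","D")}; both classes must
#'   be present.
#' @param prob Predicted disorder probabilities.
#' @param n_boot Bootstrap replicas (default 2000; 0 skips the CI).
#' @param seed Integer seed for the bootstrap (mandatory when
#'   \code{n_boot > 0}).
#' @param curve Emit curve points (default TRUE).
#' @return List of class \code{roc_result}: \code{auc}, \code{ci}
#'   (length 2), \code{roc} (data frame threshold/fpr/tpr), \code{pr}
#'   (data frame threshold/recall/precision).
#' @export
roc_auc <- function(truth, prob, n_boot = 2000L, seed, curve = TRUE) {
  stopifnot(length(truth) == length(prob))
  pos <- truth == "D"
  if (!any(pos) || all(pos))
    stop("both classes must be present for ROC analysis")
  rank_auc <- function(p, ispos) {
    r <- rank(p)   # mean ranks on ties = tie-corrected Mann-Whitney
    np <- sum(ispos)
    (sum(r[ispos]) - np * (np + 1) / 2) / (np * (sum(!ispos)))
  }
  auc <- rank_auc(prob, pos)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (missing(seed)) stop("a seed is mandatory for the bootstrap CI")
    ip <- which(pos); io <- which(!pos)
    boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      i <- c(sample(ip, length(ip), replace = TRUE),
             sample(io, length(io), replace = TRUE))
      rank_auc(prob[i], pos[i])
    }, 0))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  }
  out <- list(auc = auc, ci = ci, n_boot = n_boot)
  if (curve) {
    thr <- sort(unique(prob), decreasing = TRUE)
    np <- sum(pos); no <- sum(!pos)
    tp <- vapply(thr, function(t) sum(prob >= t & pos), 0)
    fp <- vapply(thr, function(t) sum(prob >= t & !pos), 0)
    out$roc <- data.frame(threshold = c(Inf, thr),
                          fpr = c(0, fp / no), tpr = c(0, tp / np))
    out$pr <- data.frame(threshold = thr, recall = tp / np,
                         precision = tp / pmax(tp + fp, 1))
  }
  structure(out, class = "roc_result")
}

#' Fold assignment for cross-validation
#'
#' Residue-level folds put global evaluation-unit index i (0-based, in
#' dataset order) into fold \code{i mod k}; sequence-level folds put chain
#' j into fold \code{j mod k} and carry all its residues with it, so a
#' chain is never split across folds.  Deterministic in the input order.
#'
#' @param ids Per-unit chain identifier (one entry per residue).
#' @param kind \code{"residue"} or \code{"sequence"}.
#' @param k Number of folds (>= 2).
#' @return Integer fold id (1..k) per unit.
#' @export
make_folds <- function(ids, kind = c("residue", "sequence"), k = 10L) {
  kind <- match.arg(kind)
  if (k < 2L) stop("need at least 2 folds")
  n_units <- if (kind == "residue") length(ids) else length(unique(ids))
  if (n_units < k) stop("fewer ", kind, " units (", n_units,
                        ") than folds (", k, ")")
  if (kind == "residue") {
    (seq_along(ids) - 1L) %% k + 1L
  } else {
    j <- match(ids, unique(ids)) - 1L
    j %% k + 1L
  }
}

#' Train/test window-overlap probability for residue-level splitting
#'
#' Residue-level fold assignment can place two residues of one chain in
#' training and test folds whose windows overlap.  The probability of such
#' an overlap is \eqn{(100/9)\,(W-1)/(N^2 L)} for N chains of expected
#' length L and window size W.
#'
#' @param n_seq Number of chains N.
#' @param mean_length Expected chain length.
#' @param window Window size.
#' @return The overlap probability.
#' @export
overlap_probability <- function(n_seq, mean_length, window) {
  stopifnot(n_seq > 0, mean_length > 0, window >= 1)
  (100 / 9) * (window - 1) / (n_seq^2 * mean_length)
}

#' k-fold cross-validation of the full pipeline
#'
#' For each fold: the scaler is fitted and disorder rows oversampled on the
#' training portion only, the classifier trained, and the held-out portion
#' predicted.  Unknown-labelled residues are excluded from both training
#' and evaluation (they still contributed as window neighbours during
#' featurization).  Reports per-fold metrics, their mean and standard
#' deviation, and a pooled report over all held-out residues (with AUC and
#' per-chain content MAE).
#'
#' @param x Unscaled windowed feature matrix for the whole dataset.
#' @param meta Per-row back-references from [featurize_dataset()].
#' @param hp A [hyper_params()] object.
#' @param k Number of folds (default 10).
#' @param split \code{"residue"} or \code{"sequence"} fold construction.
#' @param seed Integer seed (mandatory).
#' @param n_boot Bootstrap replicas for the pooled AUC CI.
#' @param optimize Run [grid_search()] on a 5\% subset of the evaluated
#'   rows first and use its (cost, gamma) for every fold.
#' @param calib_max Calibration row cap passed to [train_predictor()].
#' @return List of class \code{cv_result}: \code{folds} (list of
#'   \code{metric_report}), \code{summary} (mean/sd data frame),
#'   \code{pooled} (\code{metric_report} with AUC and MAE),
#'   \code{pooled_auc_by_fold}, \code{pred} (held-out predictions),
#'   \code{grid} (when optimized), \code{hp}, \code{seed}.
#' @export
cross_validate <- function(x, meta, hp = hyper_params(), k = 10L,
                           split = c("residue", "sequence"), seed,
                           n_boot = 2000L, optimize = FALSE,
                           calib_max = 5000L) {
  split <- match.arg(split)
  if (missing(seed)) stop("a seed is mandatory for cross_validate")
  keep <- meta$label != "U"
  xk <- x[keep, , drop = FALSE]
  mk <- meta[keep, , drop = FALSE]
  fold <- make_folds(mk$id, split, k)

  grid <- NULL
  if (optimize) {
    # optimization layer: one seeded grid search on a 5% subset; the
    # subset is scaled with its own extrema (training-data-only rule)
    gs_scaler <- fit_scaler(xk)
    grid <- grid_search(apply_scaler(gs_scaler, xk), mk$label,
                        subset_fraction = 0.05, seed = seed + 101L)
    hp$cost <- unname(grid$best["cost"])
    hp$gamma <- unname(grid$best["gamma"])
  }

  prob <- numeric(nrow(xk)); call <- character(nrow(xk))
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(mk$label[tr])) < 2L)
      stop("training portion of fold ", f, " lacks a class")
    model <- train_predictor(xk[tr, , drop = FALSE], mk$label[tr], hp,
                             seed = seed + f, calib_max = calib_max)
    pred <- predict_disorder(model, xk[!tr, , drop = FALSE])
    prob[!tr] <- pred$prob
    call[!tr] <- pred$call
    fold_reports[[f]] <- binary_metrics(confusion(mk$label[!tr], pred$call))
  }

  metric_names <- c("SENS", "SPEC", "ACC", "Sw", "PPV", "MCC")
  per_fold <- vapply(fold_reports,
                     function(r) unlist(r[metric_names]),
                     numeric(length(metric_names)))
  summary_df <- data.frame(metric = metric_names,
                           mean = rowMeans(per_fold),
                           sd = apply(per_fold, 1, stats::sd))

  pooled <- binary_metrics(confusion(mk$label, call))
  roc <- roc_auc(mk$label, prob, n_boot = n_boot, seed = seed + 500L,
                 curve = FALSE)
  pooled$AUC <- roc$auc
  pooled$AUC_CI <- roc$ci
  by_chain <- split(seq_len(nrow(mk)), mk$id)
  pooled$MAE <- content_mae(
    vapply(by_chain, function(i) mean(mk$label[i] == "D"), 0),
    vapply(by_chain, function(i) mean(call[i] == "D"), 0))
  auc_by_fold <- vapply(seq_len(k), function(f) {
    i <- fold == f
    if (length(unique(mk$label[i])) < 2L) return(NA_real_)
    roc_auc(mk$label[i], prob[i], n_boot = 0L, curve = FALSE)$auc
  }, 0)

  structure(list(folds = fold_reports, summary = summary_df,
                 pooled = pooled, pooled_auc_by_fold = auc_by_fold,
                 pred = cbind(mk, data.frame(prob = prob, call = call,
                                             fold = fold)),
                 grid = grid, hp = hp, seed = seed, k = k, split = split),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s-level splitting)\n", x$k,
              x$split))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %.3f (%.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  cat("pooled:\n")
  print(x$pooled)
  invisible(x)
}

#' Write an evaluation report as both text and key-value files
#'
#' @param report A \code{metric_report}.
#' @param path Base path; writes \code{<path>.txt} (human-readable) and
#'   \code{<path>.tsv} (machine-readable key-value pairs).
#' @export
write_report <- function(report, path) {
  txt <- utils::capture.output(print(report))
  writeLines(txt, paste0(path, ".txt"))
  keys <- c("TP", "TN", "FP", "FN", "SENS", "SPEC", "ACC", "Sw", "PPV",
            "MCC", "AUC", "MAE")
  vals <- vapply(keys, function(k) {
    v <- report[[k]]
    if (is.null(v) || is.na(v)) "NA" else format(v, digits = 10)
  }, "")
  writeLines(paste(keys, vals, sep = "\t"), paste0(path, ".tsv"))
  invisible(path)
}
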