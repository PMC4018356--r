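# Confusion-matrix metrics, ROC/AUC, cross-validation drivers and the
# descriptor-vs-activity statistics.

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth character vectors (`"inhibitor"` positive).
#' @return list with `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- predicted == "inhibitor"
  t <- truth == "inhibitor"
  list(TP = sum(p & t), FN = sum(!p & t), TN = sum(!p & !t), FP = sum(p & !t))
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' per-class precisions `Q_i = TP/(TP+FP)` and `Q_ni = TN/(TN+FN)`, overall
#' accuracy `Q`, and the Matthews coefficient
#' `C = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` with the
#' standard convention `C = 0` when any denominator factor vanishes. A
#' metric whose own denominator is zero is returned as `NA` (flagged
#' undefined).
#'
#' @param counts list or named vector with `TP`, `FN`, `TN`, `FP`.
#' @return list of class `metrics_report` with `SE`, `SP`, `Q_i`, `Q_ni`,
#'   `Q`, `C` (and the counts).
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FN <- as.numeric(counts[["FN"]])
  TN <- as.numeric(counts[["TN"]]); FP <- as.numeric(counts[["FP"]])
  if (any(c(TP, FN, TN, FP) < 0)) stop("negative confusion counts")
  tot <- TP + FN + TN + FP
  if (tot == 0) stop("all confusion counts are zero")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  prod_f <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  C <- if (prod_f > 0) (TP * TN - FP * FN) / sqrt(prod_f) else 0
  structure(list(
    TP = TP, FN = FN, TN = TN, FP = FP,
    SE = sdiv(TP, TP + FN), SP = sdiv(TN, TN + FP),
    Q_i = sdiv(TP, TP + FP), Q_ni = sdiv(TN, TN + FN),
    Q = (TP + TN) / tot, C = C
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "TP=%d FN=%d TN=%d FP=%d | SE=%.3f SP=%.3f Q_i=%.3f Q_ni=%.3f Q=%.3f C=%.3f\n",
    x$TP, x$FN, x$TN, x$FP, x$SE, x$SP, x$Q_i, x$Q_ni, x$Q, x$C))
  invisible(x)
}

# half-up rounding to match printed-table presentation
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the distinct score values as thresholds (predict positive when
#' score exceeds the threshold) and connects the (FPR, TPR) points; the AUC
#' is the trapezoidal area, which equals the normalized Mann-Whitney pair
#' count with ties contributing half credit.
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param labels `"inhibitor"` / `"non_inhibitor"` truth labels.
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- labels == "inhibitor"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # group ties: all examples with an equal score move together
  grp_end <- c(which(diff(ss) != 0), length(ss))
  tp <- cumsum(ys)[grp_end]; fp <- grp_end - tp
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  auc <- sum((fpr[-1] - fpr[-length(fpr)]) *
             (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# fold assignment; redraws when a fold misses a class (up to 5 attempts)
make_folds <- function(labels, k, seed, stratified = TRUE) {
  n <- length(labels)
  if (k < 2L) stop("k must be at least 2")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draw <- function() {
    if (stratified) {
      id <- integer(n)
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        if (length(idx) < k)
          stop(sprintf("class '%s' has fewer examples (%d) than folds (%d)",
                       cl, length(idx), k))
        id[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      id
    } else {
      sample(rep_len(seq_len(k), n))
    }
  }
  for (attempt in seq_len(5L)) {
    id <- draw()
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[id != f])) > 1L, FALSE))
    if (ok) return(id)
    warning("a fold lacked both classes; redrawing folds")
  }
  stop("could not draw folds containing both classes in every training part")
}

#' k-fold cross-validation driver
#'
#' `trainer(features, labels)` must return a function
#' `function(features) -> character labels`. Folds are deterministic given
#' the seed; the pooled confusion is the sum of per-fold confusions.
#'
#' @param trainer training closure (see above).
#' @param fsets list of feature objects, subsettable with `[`.
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratified stratify folds by class (default TRUE).
#' @return list with `per_fold` (list of `metrics_report`) and `pooled`
#'   (a `metrics_report`).
#' @export
cross_validate <- function(trainer, fsets, labels, k = 5, seed = 1,
                           stratified = TRUE) {
  labels <- as.character(labels)
  fold_id <- make_folds(labels, k, seed, stratified)
  per_fold <- vector("list", k)
  pooled <- c(TP = 0, FN = 0, TN = 0, FP = 0)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    predict_fn <- trainer(fsets[tr], labels[tr])
    pred <- predict_fn(fsets[!tr])
    cc <- confusion_counts(pred, labels[!tr])
    per_fold[[f]] <- compute_metrics(cc)
    pooled <- pooled + unlist(cc)
  }
  list(per_fold = per_fold, pooled = compute_metrics(as.list(pooled)),
       fold_id = fold_id)
}

#' Two-sample t test (Welch by default)
#'
#' Welch's unequal-variance statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. `pooled = TRUE` gives the classical
#' equal-variance Student test for strict replication of older analyses.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param pooled use the pooled-variance Student statistic.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y, pooled = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0 && mean(x) != mean(y))
    stop("degenerate samples: zero variance in both")
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (se == 0) return(list(t = 0, df = df, p = 1))
  t <- (mean(x) - mean(y)) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance sample")
  stats::cor(x, y)
}

#' Export metric reports as a tab-delimited table
#'
#' Column order mirrors the conventional benchmark-table layout:
#' TP FN TN FP SE SP Q_i Q_ni Q C (plus AUC when present).
#'
#' @param reports named list of `metrics_report` objects.
#' @param path output path (optional; when `NULL` the data.frame is
#'   returned).
#' @param aucs optional named numeric vector of AUCs.
#' @return data.frame (invisibly when written).
#' @export
export_metrics <- function(reports, path = NULL, aucs = NULL) {
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, TP = r$TP, FN = r$FN, TN = r$TN, FP = r$FP,
               SE = r$SE, SP = r$SP, Q_i = r$Q_i, Q_ni = r$Q_ni,
               Q = r$Q, C = r$C,
               AUC = if (!is.null(aucs) && nm %in% names(aucs)) aucs[[nm]]
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
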