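#' Binary classification metrics from confusion counts
#'
#' With a fall as the positive condition: sensitivity = TP/(TP+FN),
#' specificity = TN/(FP+TN), precision = TP/(TP+FP), accuracy =
#' (TP+TN)/(TP+FP+TN+FN), each expressed as a percentage.  A metric whose
#' denominator is zero is undefined and reported as `NA` (never coerced to
#' 0); undefined values are excluded from cross-validation means.
#'
#' @param counts A list or data.frame with non-negative integers `tp`, `fp`,
#'   `tn`, `fn`.
#' @return A list of class `metric_set` with `sensitivity`, `specificity`,
#'   `precision`, `accuracy` in percent (or `NA`), plus the counts.
#' @examples
#' compute_metrics(list(tp = 375, fn = 5, fp = 0, tn = 0))$sensitivity # 98.68
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(
    list(sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, fp + tn),
         precision = rate(tp, tp + fp),
         accuracy = rate(tp + tn, tp + fp + tn + fn),
         tp = tp, fp = fp, tn = tn, fn = fn),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat("  sensitivity ", fmt(x$sensitivity),
      "  specificity ", fmt(x$specificity),
      "  precision ", fmt(x$precision),
      "  accuracy ", fmt(x$accuracy), "\n", sep = "")
  invisible(x)
}

.count_confusion <- function(predicted_fall, truth_fall) {
  list(tp = sum(predicted_fall & truth_fall),
       fp = sum(predicted_fall & !truth_fall),
       tn = sum(!predicted_fall & !truth_fall),
       fn = sum(!predicted_fall & truth_fall))
}

#' Per-activity confusion table
#'
#' Tabulates detector decisions against ground truth separately for every
#' activity: predicted-fall and predicted-ADL counts, and sensitivity and
#' false-negative rate for fall activities or specificity and false-positive
#' rate for ADLs (percentages, 2 d.p. when printed).
#'
#' @param decisions Character vector of decisions (`"Fall"`/`"ADL"`), or the
#'   data.frame returned by [predict.fall_detector()].
#' @param labels Character vector of ground-truth activity names.
#' @return A data.frame (class `activity_confusion`) with one row per
#'   activity: `activity`, `is_fall`, `n`, `predicted_fall`,
#'   `predicted_adl`, `sensitivity`, `specificity`, `fp_rate`, `fn_rate`.
#' @export
per_activity_confusion <- function(decisions, labels) {
  if (is.data.frame(decisions)) decisions <- decisions$decision
  stopifnot(length(decisions) == length(labels))
  voc <- activity_vocabulary()
  acts <- unique(c(voc$name[voc$name %in% labels],
                   setdiff(labels, voc$name)))
  rows <- lapply(acts, function(a) {
    sel <- labels == a
    fall <- is_fall_activity(a)
    pf <- sum(decisions[sel] == "Fall")
    pa <- sum(sel) - pf
    data.frame(
      activity = a, is_fall = fall, n = sum(sel),
      predicted_fall = pf, predicted_adl = pa,
      sensitivity = if (fall) 100 * pf / sum(sel) else NA_real_,
      specificity = if (!fall) 100 * pa / sum(sel) else NA_real_,
      fp_rate = if (!fall) 100 * pf / sum(sel) else NA_real_,
      fn_rate = if (fall) 100 * pa / sum(sel) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("activity_confusion", "data.frame")
  out
}

#' @export
print.activity_confusion <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("sensitivity", "specificity", "fp_rate", "fn_rate"))
    y[[col]] <- ifelse(is.na(y[[col]]), "--", sprintf("%.2f", y[[col]]))
  print(y, row.names = FALSE)
  invisible(x)
}

# stratified fold assignment: class proportions preserved per fold, every
# element tested exactly once per round
.stratified_folds <- function(is_fall, k) {
  folds <- integer(length(is_fall))
  for (cls in unique(is_fall)) {
    idx <- sample(which(is_fall == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' The evaluation protocol: in each of `rounds` rounds the dataset is
#' stratified-randomly partitioned into `k` folds; for each fold a detector
#' is fit on the remaining k-1 folds (thresholds plus phase classifier for
#' the hierarchical method; the whole-frame SVM for the baseline) and
#' evaluated on the held-out fold.  Per-fold metrics are aggregated into
#' per-round means/standard deviations and an overall mean.  Undefined
#' (zero-denominator) fold metrics are excluded from means.
#'
#' @param x A list of records/frames/`annotated_record`s.
#' @param is_fall Logical ground truth; derived from labels when `NULL`.
#' @param k Number of folds (>= 2; default 5).
#' @param rounds Number of repetitions (default 5).
#' @param seed Integer seed for the partitions.
#' @param method `"knowledge"` (the hierarchical detector, default) or
#'   `"baseline"` (whole-frame SVM).
#' @param config A [detector_config()].
#' @return An object of class `fall_cv`: `folds` (data.frame of per-fold
#'   counts and metrics), `rounds` (per-round mean and sd of each metric),
#'   `overall` (named means across all folds), `decisions` (per-record
#'   decisions across all rounds, for aggregated confusion tables), plus
#'   `k`, `n_rounds`, `method`.
#' @examples
#' \donttest{
#' ds <- gen_dataset(30, 30, seed = 2)
#' cv <- run_cross_validation(ds, k = 5, rounds = 1, seed = 3)
#' cv$overall
#' }
#' @export
run_cross_validation <- function(x, is_fall = NULL, k = 5, rounds = 5,
                                 seed = 1,
                                 method = c("knowledge", "baseline"),
                                 config = detector_config()) {
  method <- match.arg(method)
  stopifnot(k >= 2)
  frames <- lapply(x, as_frame, pad_policy = config$pad_policy)
  n <- length(frames)
  if (n < k)
    stop("dataset (", n, " frames) smaller than k = ", k, call. = FALSE)
  if (is.null(is_fall)) {
    labels <- vapply(frames, function(f)
      if (is.null(f$label)) NA_character_ else f$label, character(1))
    if (anyNA(labels))
      stop("is_fall not supplied and some frames carry no activity label",
           call. = FALSE)
    is_fall <- is_fall_activity(labels)
  }
  is_fall <- as.logical(is_fall)
  stopifnot(length(is_fall) == n)
  metric_names <- c("sensitivity", "specificity", "precision", "accuracy")

  rows <- list()
  dec_rows <- list()
  .with_seed(seed, {
    for (r in seq_len(rounds)) {
      # re-draw the partition if some training split lacks a class
      repeat {
        folds <- .stratified_folds(is_fall, k)
        ok <- all(vapply(seq_len(k), function(f)
          length(unique(is_fall[folds != f])) == 2L, logical(1)))
        if (ok) break
      }
      for (f in seq_len(k)) {
        test <- folds == f
        fit <- if (method == "knowledge")
          fall_detector(frames[!test], is_fall[!test], config)
        else
          frame_classifier(frames[!test], is_fall[!test], config)
        pred <- if (method == "knowledge")
          predict(fit, frames[test])$decision
        else
          predict(fit, frames[test])
        m <- compute_metrics(.count_confusion(pred == "Fall",
                                              is_fall[test]))
        rows[[length(rows) + 1L]] <- data.frame(
          round = r, fold = f, n_test = sum(test),
          tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
          sensitivity = m$sensitivity, specificity = m$specificity,
          precision = m$precision, accuracy = m$accuracy)
        dec_rows[[length(dec_rows) + 1L]] <- data.frame(
          round = r, fold = f, index = which(test), decision = pred)
      }
    }
  })
  folds_df <- do.call(rbind, rows)
  round_stats <- do.call(rbind, lapply(split(folds_df, folds_df$round),
    function(d) {
      means <- vapply(metric_names, function(mn)
        mean(d[[mn]], na.rm = TRUE), numeric(1))
      sds <- vapply(metric_names, function(mn)
        stats::sd(d[[mn]], na.rm = TRUE), numeric(1))
      data.frame(round = d$round[1L], t(means),
                 setNames(as.data.frame(t(sds)),
                          paste0(metric_names, "_sd")))
    }))
  overall <- vapply(metric_names, function(mn)
    mean(folds_df[[mn]], na.rm = TRUE), numeric(1))
  structure(list(folds = folds_df, rounds = round_stats, overall = overall,
                 decisions = do.call(rbind, dec_rows),
                 k = k, n_rounds = rounds, method = method),
            class = "fall_cv")
}

#' @export
print.fall_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d round(s) — %s method\n",
              x$k, x$n_rounds, x$method))
  cat(format_cv_report(x), sep = "\n")
  invisible(x)
}

#' Render a cross-validation report as text
#'
#' Plain-text table in the round-by-round layout: one row per metric, one
#' column per round as "mean (sd)", and an overall mean column.
#'
#' @param cv A `fall_cv` from [run_cross_validation()].
#' @return Character vector of lines.
#' @export
format_cv_report <- function(cv) {
  metric_names <- c("sensitivity", "specificity", "precision", "accuracy")
  hdr <- c("Metric (%)", paste("Round", seq_len(cv$n_rounds)), "Mean")
  body <- vapply(metric_names, function(mn) {
    cells <- sprintf("%.2f (%.2f)", cv$rounds[[mn]],
                     cv$rounds[[paste0(mn, "_sd")]])
    c(mn, cells, sprintf("%.2f", cv$overall[[mn]]))
  }, character(cv$n_rounds + 2L))
  tab <- rbind(hdr, t(body))
  widths <- apply(nchar(tab), 2L, max)
  apply(tab, 1L, function(row)
    paste(mapply(formatC, row, width = widths), collapse = "  "))
}

#' Export a cross-validation report as CSV
#'
#' Writes the per-fold table (`<path>`), with per-round and overall summary
#' rows appended by `summary = TRUE`.
#'
#' @param cv A `fall_cv`.
#' @param path Output CSV path.
#' @param summary Also write `<path base>_rounds.csv` with the round
#'   summaries.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path, summary = TRUE) {
  utils::write.csv(cv$folds, path, row.names = FALSE)
  if (summary) {
    base <- sub("\\.csv$", "", path)
    utils::write.csv(cv$rounds, paste0(base, "_rounds.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}
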