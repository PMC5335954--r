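PHASE_LEVELS <- c("FreeFall", "Impact", "Rest")

.fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1  # constant features pass through uncentered-scaled
  list(center = ctr, scale = scl)
}

.apply_scaler <- function(X, scaler) {
  scale(X, center = scaler$center, scale = scaler$scale)
}

.feature_matrix <- function(vectors) {
  X <- do.call(rbind, vectors)
  if (ncol(X) != 54L)
    stop("feature vectors must have length 54, got ", ncol(X), call. = FALSE)
  X
}

#' Fit the hierarchical fall detector
#'
#' The single fitting entry point of the package.  From labeled training
#' data it learns both stages of the hierarchy:
#'
#' 1. **Threshold stage** — the four triage thresholds of
#'    [fit_thresholds()], computed from every training frame's norm extrema.
#' 2. **Knowledge stage** — a 3-class phase classifier trained on the fall
#'    frames only: each fall frame is segmented by [segment_phases()], its
#'    free-fall, impact and rest spans are featurized (54 statistics each,
#'    [extract_features()]), features are z-scored with a scaler fit on the
#'    training features, and a one-vs-one linear-kernel SVM (3 classes,
#'    hence 3 underlying binary classifiers) is fit on the phase labels.
#'
#' At prediction time ([detect()] / `predict()`) a frame triaged `"Fall"` or
#' `"ADL"` is decided immediately; an `"Unidentified"` frame is segmented,
#' its phases classified, and a fall is declared only when the predicted
#' sequence is exactly free fall, impact, rest.
#'
#' @param x A list of [accel_record()]s, `accel_frame`s, or
#'   `annotated_record`s (mixed is fine).
#' @param is_fall Logical ground truth, one per element of `x`.  When `NULL`
#'   it is derived from each element's activity label via
#'   [is_fall_activity()].
#' @param config A [detector_config()]; stored in the model so predictions
#'   reuse the fit-time conventions.
#' @return An object of class `fall_detector` with components `thresholds`,
#'   `scaler`, `svm`, `config`, `n_fall`, `n_adl`.
#' @seealso [detect()], [predict.fall_detector()], [frame_classifier()]
#' @examples
#' set.seed(1)
#' ds <- gen_dataset(n_falls = 12, n_adls = 12, seed = 7)
#' fit <- fall_detector(ds)
#' fit
#' @export
fall_detector <- function(x, is_fall = NULL, config = detector_config()) {
  frames <- lapply(x, as_frame, pad_policy = config$pad_policy)
  if (is.null(is_fall)) {
    labels <- vapply(frames, function(f)
      if (is.null(f$label)) NA_character_ else f$label, character(1))
    if (anyNA(labels))
      stop("is_fall not supplied and some frames carry no activity label",
           call. = FALSE)
    is_fall <- is_fall_activity(labels)
  }
  is_fall <- as.logical(is_fall)
  stopifnot(length(is_fall) == length(frames))

  ex <- lapply(frames, frame_extrema)
  thresholds <- fit_thresholds(ex, is_fall)  # errors if a class is absent

  fall_frames <- frames[is_fall]
  phase_feats <- lapply(fall_frames, function(f)
    featurize_phases(f, config = config))
  X <- .feature_matrix(unlist(phase_feats, recursive = FALSE))
  y <- factor(rep(PHASE_LEVELS, times = length(fall_frames)),
              levels = PHASE_LEVELS)
  scaler <- .fit_scaler(X)
  svm <- e1071::svm(x = .apply_scaler(X, scaler), y = y,
                    kernel = "linear", cost = config$cost, scale = FALSE)

  structure(
    list(thresholds = thresholds, scaler = scaler, svm = svm,
         config = config,
         n_fall = sum(is_fall), n_adl = sum(!is_fall)),
    class = "fall_detector")
}

#' @export
print.fall_detector <- function(x, ...) {
  cat("Hierarchical fall detector\n")
  cat(sprintf("  trained on %d fall and %d ADL frames\n", x$n_fall, x$n_adl))
  cat(sprintf("  thresholds (g): fall if v > %.3f & w > %.3f; ADL if v < %.3f & w < %.3f\n",
              x$thresholds$t_fall_xyz, x$thresholds$t_fall_hori,
              x$thresholds$t_adl_xyz, x$thresholds$t_adl_hori))
  cat(sprintf("  phase classifier: one-vs-one linear SVM, %d classes, cost %g\n",
              length(x$svm$levels), x$config$cost))
  invisible(x)
}

#' @export
summary.fall_detector <- function(object, ...) {
  print(object)
  cat(sprintf("  support vectors: %d (of %d phase training vectors)\n",
              nrow(object$svm$SV), 3L * object$n_fall))
  cat(sprintf("  conventions: var %s, sd %s, skew %s, kurt %s, coronal pair %s\n",
              object$config$var_denom, object$config$sd_denom,
              object$config$skew_form, object$config$kurt_form,
              object$config$vert_pair))
  invisible(object)
}

#' @export
coef.fall_detector <- function(object, ...) {
  unlist(unclass(object$thresholds))
}

#' Classify the phases of a frame
#'
#' Segments a frame into its three phase spans, featurizes each, and labels
#' them with the model's phase SVM.  Timestamps are each phase's start time
#' in seconds from the frame start.
#'
#' @param model A fitted [fall_detector()].
#' @param frame An `accel_frame` or [accel_record()].
#' @return A list of class `phase_prediction` with `phase` (character, length
#'   3) and `time` (numeric, strictly increasing, seconds).
#' @export
predict_phases <- function(model, frame) {
  stopifnot(inherits(model, "fall_detector"))
  frame <- as_frame(frame, pad_policy = model$config$pad_policy)
  seg <- segment_phases(frame, model$config)
  X <- .feature_matrix(featurize_phases(frame, seg, model$config))
  pred <- stats::predict(model$svm, .apply_scaler(X, model$scaler))
  structure(
    list(phase = as.character(pred),
         time = (c(seg$free_fall[1L], seg$impact[1L], seg$rest[1L]) - 1L) /
           frame$sample_rate,
         situation = seg$situation),
    class = "phase_prediction")
}

#' @export
print.phase_prediction <- function(x, ...) {
  cat("<phase_prediction> ",
      paste(sprintf("%s@%.3fs", x$phase, x$time), collapse = " -> "),
      if (check_temporal_order(x)) "  [fall order]" else "  [not fall order]",
      "\n", sep = "")
  invisible(x)
}

#' Temporal-order post-processing rule
#'
#' A phase sequence is accepted as a fall only when it is exactly
#' (FreeFall, Impact, Rest) — the defined temporal order of the multiphase
#' fall model.  Of the 27 possible 3-label sequences exactly one passes.
#'
#' @param prediction A `phase_prediction`, or a character vector of 3 phase
#'   names.
#' @return `TRUE` iff the sequence is `FreeFall, Impact, Rest` in order.
#' @export
check_temporal_order <- function(prediction) {
  p <- if (is.character(prediction)) prediction else prediction$phase
  length(p) == 3L && identical(unname(p), PHASE_LEVELS)
}

#' Hierarchical detection on one record
#'
#' Runs the full pipeline on a single record: preprocessing (norms, critical
#' point, 513-sample frame), threshold triage, and — for unidentified frames
#' only — phase classification plus the temporal-order rule.
#'
#' @param record An [accel_record()], `accel_frame`, or `annotated_record`.
#' @param model A fitted [fall_detector()].
#' @return A list of class `fall_decision`: `decision` (`"Fall"`/`"ADL"`),
#'   `stage` (`"threshold"` or `"knowledge"`), `prediction` (the
#'   `phase_prediction`, `NULL` for threshold-stage decisions), and the
#'   frame extrema `v`, `w`.
#' @export
detect <- function(record, model) {
  stopifnot(inherits(model, "fall_detector"))
  frame <- as_frame(record, pad_policy = model$config$pad_policy)
  ex <- frame_extrema(frame)
  tri <- triage(ex, model$thresholds)
  if (tri != "Unidentified")
    return(structure(list(decision = tri, stage = "threshold",
                          prediction = NULL, v = ex$v, w = ex$w),
                     class = "fall_decision"))
  pp <- predict_phases(model, frame)
  structure(
    list(decision = if (check_temporal_order(pp)) "Fall" else "ADL",
         stage = "knowledge", prediction = pp, v = ex$v, w = ex$w),
    class = "fall_decision")
}

#' @export
print.fall_decision <- function(x, ...) {
  cat(sprintf("<fall_decision> %s (%s stage; v = %.2f g, w = %.2f g)\n",
              x$decision, x$stage, x$v, x$w))
  if (!is.null(x$prediction)) print(x$prediction)
  invisible(x)
}

#' Predict method for fall detectors
#'
#' Applies [detect()] to one record or a list of records and tabulates the
#' decisions.
#'
#' @param object A fitted [fall_detector()].
#' @param newdata A record/frame or a list of them.
#' @param ... Unused.
#' @return A data.frame with one row per record: `decision`, `stage`,
#'   `phases` (the predicted sequence, `NA` for threshold-stage rows), `v`,
#'   `w`.
#' @export
predict.fall_detector <- function(object, newdata, ...) {
  if (inherits(newdata, c("accel_record", "accel_frame", "annotated_record")))
    newdata <- list(newdata)
  dec <- lapply(newdata, detect, model = object)
  data.frame(
    decision = vapply(dec, `[[`, character(1), "decision"),
    stage = vapply(dec, `[[`, character(1), "stage"),
    phases = vapply(dec, function(d)
      if (is.null(d$prediction)) NA_character_
      else paste(d$prediction$phase, collapse = ">"), character(1)),
    v = vapply(dec, `[[`, numeric(1), "v"),
    w = vapply(dec, `[[`, numeric(1), "w"),
    stringsAsFactors = FALSE)
}

#' Persist and reload a fitted detector
#'
#' The bundle contains the thresholds, scaler, SVM and configuration, so a
#' reloaded model reproduces detection without retraining.
#'
#' @param model A fitted [fall_detector()] or [frame_classifier()].
#' @param path Bundle file path.
#' @return `save_detector()`: `path` invisibly; `load_detector()`: the model.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, c("fall_detector", "frame_classifier")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("fall_detector", "frame_classifier")))
    stop("not a detector bundle: ", path, call. = FALSE)
  model
}

#' Whole-frame machine-learning baseline
#'
#' The ablation of the multiphase model: a binary linear SVM on the 54
#' features of the unsegmented 513-sample frame.  It uses the identical
#' feature set as the phase classifier so comparing the two isolates the
#' contribution of multiphase segmentation.
#'
#' @inheritParams fall_detector
#' @return An object of class `frame_classifier` with `scaler`, `svm`,
#'   `config`, `n_fall`, `n_adl`.
#' @export
frame_classifier <- function(x, is_fall = NULL, config = detector_config()) {
  frames <- lapply(x, as_frame, pad_policy = config$pad_policy)
  if (is.null(is_fall)) {
    labels <- vapply(frames, function(f)
      if (is.null(f$label)) NA_character_ else f$label, character(1))
    if (anyNA(labels))
      stop("is_fall not supplied and some frames carry no activity label",
           call. = FALSE)
    is_fall <- is_fall_activity(labels)
  }
  is_fall <- as.logical(is_fall)
  if (!any(is_fall) || !any(!is_fall))
    stop("baseline training needs both classes", call. = FALSE)
  X <- .feature_matrix(lapply(frames, featurize_frame, config = config))
  y <- factor(ifelse(is_fall, "Fall", "ADL"), levels = c("Fall", "ADL"))
  scaler <- .fit_scaler(X)
  svm <- e1071::svm(x = .apply_scaler(X, scaler), y = y,
                    kernel = "linear", cost = config$cost, scale = FALSE)
  structure(list(scaler = scaler, svm = svm, config = config,
                 n_fall = sum(is_fall), n_adl = sum(!is_fall)),
            class = "frame_classifier")
}

#' @export
print.frame_classifier <- function(x, ...) {
  cat("Whole-frame fall/ADL classifier (linear SVM baseline)\n")
  cat(sprintf("  trained on %d fall and %d ADL frames; cost %g\n",
              x$n_fall, x$n_adl, x$config$cost))
  invisible(x)
}

#' @export
predict.frame_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, c("accel_record", "accel_frame", "annotated_record")))
    newdata <- list(newdata)
  frames <- lapply(newdata, as_frame, pad_policy = object$config$pad_policy)
  X <- .feature_matrix(lapply(frames, featurize_frame,
                              config = object$config))
  as.character(stats::predict(object$svm, .apply_scaler(X, object$scaler)))
}
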