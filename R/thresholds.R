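#' Frame extrema used by the threshold stage
#'
#' The triage stage summarises a frame by two numbers: `v`, the maximum
#' tri-axial norm over the frame, and `w`, the maximum horizontal-plane norm.
#'
#' @param frame An `accel_frame` (or anything [as_frame()] accepts).
#' @return A list of class `frame_extrema` with numeric `v` and `w` (g).
#' @export
frame_extrema <- function(frame) {
  frame <- as_frame(frame)
  nx <- compute_norms(frame)
  structure(list(v = max(nx$norm_xyz), w = max(nx$norm_hori)),
            class = "frame_extrema")
}

#' Learn the four triage thresholds
#'
#' The fall thresholds are the maxima of the ADL training frames' extrema
#' (`t_fall_xyz`, `t_fall_hori`): any test frame exceeding both is more
#' extreme than every training ADL, hence an absolute fall.  The ADL
#' thresholds are the minima of the fall training frames' extrema
#' (`t_adl_xyz`, `t_adl_hori`): a frame below both is milder than every
#' training fall.  Frames between the bands are left to the knowledge stage.
#'
#' @param extrema A list of `frame_extrema` (or a data.frame with columns
#'   `v`, `w`).
#' @param is_fall Logical vector of ground-truth classes, one per frame.
#' @return A list of class `fall_thresholds` with fields `t_fall_xyz`,
#'   `t_fall_hori`, `t_adl_xyz`, `t_adl_hori` (g).
#' @examples
#' ex <- data.frame(v = c(4, 5, 2, 2.5), w = c(3, 4, 1, 1.5))
#' fit_thresholds(ex, is_fall = c(TRUE, TRUE, FALSE, FALSE))
#' @export
fit_thresholds <- function(extrema, is_fall) {
  if (is.data.frame(extrema)) {
    v <- extrema$v; w <- extrema$w
  } else {
    v <- vapply(extrema, `[[`, numeric(1), "v")
    w <- vapply(extrema, `[[`, numeric(1), "w")
  }
  is_fall <- as.logical(is_fall)
  stopifnot(length(v) == length(is_fall))
  if (!any(is_fall))
    stop("cannot fit thresholds: no fall frames in the training set",
         call. = FALSE)
  if (!any(!is_fall))
    stop("cannot fit thresholds: no ADL frames in the training set",
         call. = FALSE)
  structure(
    list(t_fall_xyz  = max(v[!is_fall]),
         t_fall_hori = max(w[!is_fall]),
         t_adl_xyz   = min(v[is_fall]),
         t_adl_hori  = min(w[is_fall])),
    class = "fall_thresholds")
}

#' @export
print.fall_thresholds <- function(x, ...) {
  cat("<fall_thresholds> (g)\n")
  cat(sprintf("  fall if  v > %.3f and w > %.3f\n", x$t_fall_xyz, x$t_fall_hori))
  cat(sprintf("  ADL  if  v < %.3f and w < %.3f\n", x$t_adl_xyz, x$t_adl_hori))
  cat("  otherwise unidentified (knowledge stage)\n")
  invisible(x)
}

#' Three-way threshold triage
#'
#' Applies the threshold classifier to a frame's extrema: `"Fall"` when both
#' extrema strictly exceed the fall thresholds, `"ADL"` when both are
#' strictly below the ADL thresholds, `"Unidentified"` otherwise.
#' Inequalities are strict, so a frame sitting exactly on a threshold is
#' deferred to the knowledge stage.
#'
#' @param extrema A `frame_extrema` (or a list with `v` and `w`).
#' @param thresholds A `fall_thresholds`.
#' @return One of `"Fall"`, `"ADL"`, `"Unidentified"`.
#' @export
triage <- function(extrema, thresholds) {
  stopifnot(inherits(thresholds, "fall_thresholds"))
  v <- extrema$v; w <- extrema$w
  if (v > thresholds$t_fall_xyz && w > thresholds$t_fall_hori) return("Fall")
  if (v < thresholds$t_adl_xyz && w < thresholds$t_adl_hori) return("ADL")
  "Unidentified"
}
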