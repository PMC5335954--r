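#' Euclidean norms of a tri-axial record
#'
#' Computes the per-sample Euclidean norms the detector works with:
#' `norm_xyz = sqrt(ax^2 + ay^2 + az^2)` (spatial variation of acceleration),
#' `norm_hori = sqrt(ay^2 + az^2)` (horizontal-plane change of velocity, the
#' x axis being vertical in the sensor frame), and `norm_verti`, the norm of
#' the coronal-plane pair (default `(ax, ay)`; configurable because the axis
#' pairing of the coronal plane depends on sensor mounting).
#'
#' @param record An [accel_record()], or any list with numeric `ax`, `ay`,
#'   `az` of equal length.
#' @param vert_pair Coronal-plane axis pair, `"xy"` (default) or `"xz"`.
#' @return A list of class `norm_series` with numeric vectors `norm_xyz`,
#'   `norm_hori`, `norm_verti` of the record's length.
#' @examples
#' r <- accel_record(ax = 0, ay = 3, az = 4)
#' compute_norms(r)$norm_xyz   # 5
#' @export
compute_norms <- function(record, vert_pair = c("xy", "xz")) {
  vert_pair <- match.arg(vert_pair)
  ax <- record$ax; ay <- record$ay; az <- record$az
  nv <- if (vert_pair == "xy") sqrt(ax^2 + ay^2) else sqrt(ax^2 + az^2)
  structure(list(norm_xyz = sqrt(ax^2 + ay^2 + az^2),
                 norm_hori = sqrt(ay^2 + az^2),
                 norm_verti = nv),
            class = "norm_series")
}

#' Locate the critical point
#'
#' The critical point is the sample index at which `norm_xyz` attains its
#' record-wide maximum — for a fall, the impact peak.  Ties are broken by the
#' earliest index so the result is deterministic and order-stable.
#'
#' @param norms A `norm_series` from [compute_norms()], or a numeric vector
#'   taken as `norm_xyz` directly.
#' @return A list of class `critical_point` with `index` (1-based) and
#'   `value` (the maximum norm, in g).
#' @export
find_critical_point <- function(norms) {
  v <- if (is.numeric(norms)) norms else norms$norm_xyz
  if (length(v) < 1L)
    stop("cannot locate a critical point in an empty series", call. = FALSE)
  i <- which.max(v)  # which.max returns the first maximum
  structure(list(index = i, value = v[i]), class = "critical_point")
}

# window geometry: samples before / after the critical point at 128 Hz
FRAME_PRE    <- 192L  # 1.5 s
FRAME_POST   <- 320L  # 2.5 s
FRAME_LEN    <- FRAME_PRE + 1L + FRAME_POST  # 513
CRITICAL_POS <- FRAME_PRE + 1L               # local index 193 (1-based)

#' Cut the fixed classification window around the critical point
#'
#' Every record is classified through exactly one frame: the 513 samples
#' spanning 1.5 s (192 samples) before the critical point through 2.5 s
#' (320 samples) after it, so the critical point always sits at local index
#' 193 (1-based).  When the record is too short to cover the window,
#' `pad_policy = "replicate"` (default) repeats the boundary sample and
#' records how many samples were padded on each side, so downstream stages
#' can filter; `"reject"` raises an error instead.
#'
#' @param record An [accel_record()].
#' @param critical A `critical_point` from [find_critical_point()]; computed
#'   from `record` when `NULL`.
#' @param pad_policy `"replicate"` or `"reject"`.
#' @return An object of class `accel_frame`: a list with `ax`, `ay`, `az`
#'   (length 513), `critical_index` (always 193), `pad_left`, `pad_right`,
#'   `sample_rate`, `label`, `subject_id`.
#' @examples
#' r <- gen_fall(sim_config(seed = 1))$record
#' f <- make_frame(r)
#' f$critical_index
#' @export
make_frame <- function(record, critical = NULL,
                       pad_policy = c("replicate", "reject")) {
  pad_policy <- match.arg(pad_policy)
  stopifnot(inherits(record, "accel_record"))
  if (is.null(critical)) critical <- find_critical_point(compute_norms(record))
  n <- length(record)
  ci <- critical$index
  if (ci < 1L || ci > n)
    stop("critical index out of record bounds", call. = FALSE)
  lo <- ci - FRAME_PRE
  hi <- ci + FRAME_POST
  pad_left <- max(0L, 1L - lo)
  pad_right <- max(0L, hi - n)
  if (pad_policy == "reject" && (pad_left > 0L || pad_right > 0L))
    stop(sprintf(
      "window [%d, %d] exceeds record bounds [1, %d] (pad policy 'reject')",
      lo, hi, n), call. = FALSE)
  idx <- pmin(pmax(lo:hi, 1L), n)  # replicate boundary samples
  structure(
    list(ax = record$ax[idx], ay = record$ay[idx], az = record$az[idx],
         critical_index = CRITICAL_POS,
         pad_left = pad_left, pad_right = pad_right,
         sample_rate = record$sample_rate,
         label = record$label, subject_id = record$subject_id),
    class = "accel_frame")
}

#' @export
length.accel_frame <- function(x) length(x$ax)

#' @export
print.accel_frame <- function(x, ...) {
  nx <- compute_norms(x)
  cat(sprintf(
    "<accel_frame> %d samples, critical point at index %d (peak %.2f g)\n",
    length(x), x$critical_index, nx$norm_xyz[x$critical_index]))
  if (x$pad_left > 0L || x$pad_right > 0L)
    cat(sprintf("  padded: %d left, %d right (boundary replication)\n",
                x$pad_left, x$pad_right))
  if (!is.null(x$label)) cat("  label: ", x$label, "\n", sep = "")
  invisible(x)
}

#' Coerce a record or frame to a frame
#'
#' Records are windowed via [compute_norms()], [find_critical_point()] and
#' [make_frame()]; frames pass through unchanged.
#'
#' @param x An [accel_record()] or `accel_frame`.
#' @param pad_policy Passed to [make_frame()].
#' @return An `accel_frame`.
#' @export
as_frame <- function(x, pad_policy = "replicate") {
  if (inherits(x, "accel_frame")) return(x)
  if (inherits(x, "annotated_record")) x <- x$record
  if (!inherits(x, "accel_record"))
    stop("cannot coerce ", paste(class(x), collapse = "/"),
         " to accel_frame", call. = FALSE)
  make_frame(x, pad_policy = pad_policy)
}
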