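#' Detector configuration
#'
#' Bundles the tunable conventions of the pipeline so a fitted model can
#' record exactly how its features were computed.
#'
#' @param sample_rate Sampling rate in Hz (default 128).
#' @param pad_policy Frame padding policy, see [make_frame()].
#' @param vert_pair Coronal-plane axis pair for `a_verti`, see
#'   [compute_norms()].
#' @param sd_denom,var_denom Denominator for the standard-deviation and
#'   variance features: `"n-1"` (sample estimator, default) or `"n"`.
#' @param skew_form Skewness estimator: `"g1"` (standardized third central
#'   moment, default) or `"G1"` (bias-adjusted).
#' @param kurt_form Kurtosis estimator: `"pearson"` (standardized fourth
#'   central moment, so a normal signal scores about 3; default) or
#'   `"excess"` (`pearson - 3`).
#' @param cost Margin penalty (C) of the linear SVM. Default 1.
#' @param severe_peak_g Impact-severity boundary in g separating the short
#'   (severe) from the long (mild) impact window. Default 6, the sensor's
#'   documented range limit; a peak at or above it is treated as severe.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(sample_rate = 128,
                            pad_policy = c("replicate", "reject"),
                            vert_pair = c("xy", "xz"),
                            sd_denom = c("n-1", "n"),
                            var_denom = c("n-1", "n"),
                            skew_form = c("g1", "G1"),
                            kurt_form = c("pearson", "excess"),
                            cost = 1,
                            severe_peak_g = 6) {
  structure(
    list(sample_rate = sample_rate,
         pad_policy = match.arg(pad_policy),
         vert_pair = match.arg(vert_pair),
         sd_denom = match.arg(sd_denom),
         var_denom = match.arg(var_denom),
         skew_form = match.arg(skew_form),
         kurt_form = match.arg(kurt_form),
         cost = cost,
         severe_peak_g = severe_peak_g),
    class = "detector_config")
}

#' Multiphase fall segmentation
#'
#' Partitions the classification frame into the three semantic fall phases.
#' The impact window is centred on the critical point and its length depends
#' on severity: for a peak norm above 6 g the impact is 21 samples (10 +
#' critical + 10); below 6 g it is 31 samples (10 + critical + 20), the
#' longer tail reflecting the slower settling of mild impacts.  The rest
#' phase runs from the end of the impact to the end of the frame, and the
#' free-fall phase is the 32 samples immediately before the impact.
#'
#' @param frame An `accel_frame`.
#' @param config A [detector_config()] (supplies the 6 g severity boundary;
#'   a peak exactly on the boundary is treated as severe, since a peak at
#'   the sensor's range limit indicates saturation).
#' @return A list of class `phase_segmentation` with 1-based inclusive index
#'   spans `free_fall`, `impact`, `rest` (each `c(start, end)`), the
#'   `situation` (`"severe"` or `"mild"`) and the frame `peak` in g.
#' @examples
#' f <- as_frame(gen_fall(sim_config(impact_peak = 7, seed = 42))$record)
#' segment_phases(f)
#' @export
segment_phases <- function(frame, config = detector_config()) {
  frame <- as_frame(frame)
  peak <- max(compute_norms(frame)$norm_xyz)
  severe <- peak >= config$severe_peak_g
  ci <- frame$critical_index
  impact <- if (severe) c(ci - 10L, ci + 10L) else c(ci - 10L, ci + 20L)
  structure(
    list(free_fall = c(impact[1L] - 32L, impact[1L] - 1L),
         impact = impact,
         rest = c(impact[2L] + 1L, length(frame)),
         situation = if (severe) "severe" else "mild",
         peak = peak),
    class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  span <- function(s) sprintf("[%d, %d] (%d samples)", s[1], s[2],
                              s[2] - s[1] + 1L)
  cat(sprintf("<phase_segmentation> %s impact (peak %.2f g)\n",
              x$situation, x$peak))
  cat("  free fall:", span(x$free_fall), "\n")
  cat("  impact:   ", span(x$impact), "\n")
  cat("  rest:     ", span(x$rest), "\n")
  invisible(x)
}

#' Feature vector column names
#'
#' Stable names `f1`..`f54` with a descriptive variant for export.
#'
#' @param descriptive Return `"<stat>_<signal>"` names instead of `f1..f54`.
#' @return Character vector of length 54.
#' @export
feature_names <- function(descriptive = FALSE) {
  if (!descriptive) return(paste0("f", 1:54))
  sig <- c("ax", "ay", "az", "a_norm", "a_verti", "a_hori")
  stat <- c("mean", "std", "var", "max", "min", "range", "kurtosis",
            "skewness")
  c(as.vector(t(outer(stat, sig, paste, sep = "_"))),
    "corr_ax_ay", "corr_ax_az", "corr_ay_az",
    "corr_a_norm_a_verti", "corr_a_norm_a_hori", "corr_a_verti_a_hori")
}

# central moment of order k with denominator n
.cmoment <- function(x, k) mean((x - mean(x))^k)

.skewness <- function(x, form) {
  n <- length(x)
  m2 <- .cmoment(x, 2)
  if (m2 < 1e-300) return(0)  # constant-signal convention
  g1 <- .cmoment(x, 3) / m2^1.5
  if (form == "G1" && n > 2L) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

.kurtosis <- function(x, form) {
  m2 <- .cmoment(x, 2)
  if (m2 < 1e-300) return(0)  # constant-signal convention
  b2 <- .cmoment(x, 4) / m2^2
  if (form == "excess") b2 - 3 else b2
}

.cor0 <- function(x, y) {
  # correlation with the zero convention for degenerate (constant) input:
  # rest phases can be nearly constant and must still yield finite features
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300) return(0)
  stats::cor(x, y)
}

#' Time-domain feature extraction
#'
#' Computes the 54 time-domain statistics describing a tri-axial segment:
#' mean, standard deviation, variance, maximum, minimum, range, kurtosis and
#' skewness of each of six signals — the three axes `ax`, `ay`, `az` and the
#' three Euclidean norms `a_norm` (tri-axial), `a_verti` (coronal plane) and
#' `a_hori` (horizontal plane) — plus the six pairwise correlation
#' coefficients among `ax`/`ay`/`az` and among the three norms.  Statistics
#' are ordered statistic-major (all six means, then all six standard
#' deviations, ...) and named `f1`..`f54`.
#'
#' Correlations (and skewness/kurtosis) of a constant signal are defined as
#' 0 so that near-motionless rest phases still produce finite features.
#'
#' @param seg A list or data.frame with numeric `ax`, `ay`, `az` of equal
#'   length m >= 2 (accelerations in g).
#' @param config A [detector_config()] supplying the estimator conventions.
#' @return Named numeric vector of length 54 with attribute `m` (the segment
#'   length).
#' @examples
#' extract_features(list(ax = c(1, 2, 3), ay = c(0, 0, 0), az = c(0, 0, 0)))
#' @export
extract_features <- function(seg, config = detector_config()) {
  ax <- as.numeric(seg$ax); ay <- as.numeric(seg$ay); az <- as.numeric(seg$az)
  m <- length(ax)
  if (m < 2L)
    stop("segment too short for feature extraction (m = ", m,
         ", need >= 2)", call. = FALSE)
  stopifnot(length(ay) == m, length(az) == m)
  a_norm <- sqrt(ax^2 + ay^2 + az^2)
  a_verti <- if (config$vert_pair == "xy") sqrt(ax^2 + ay^2)
             else sqrt(ax^2 + az^2)
  a_hori <- sqrt(ay^2 + az^2)
  sigs <- list(ax, ay, az, a_norm, a_verti, a_hori)

  dnm <- function(which) if (which == "n-1") m - 1 else m
  vr <- vapply(sigs, function(x) sum((x - mean(x))^2), numeric(1))
  out <- c(
    vapply(sigs, mean, numeric(1)),
    sqrt(vr / dnm(config$sd_denom)),
    vr / dnm(config$var_denom),
    vapply(sigs, max, numeric(1)),
    vapply(sigs, min, numeric(1)),
    vapply(sigs, function(x) max(x) - min(x), numeric(1)),
    vapply(sigs, .kurtosis, numeric(1), form = config$kurt_form),
    vapply(sigs, .skewness, numeric(1), form = config$skew_form),
    .cor0(ax, ay), .cor0(ax, az), .cor0(ay, az),
    .cor0(a_norm, a_verti), .cor0(a_norm, a_hori), .cor0(a_verti, a_hori))
  names(out) <- feature_names()
  attr(out, "m") <- m
  out
}

.slice_frame <- function(frame, span) {
  idx <- span[1L]:span[2L]
  list(ax = frame$ax[idx], ay = frame$ay[idx], az = frame$az[idx])
}

#' Featurize a whole frame or its three phases
#'
#' `featurize_frame()` applies [extract_features()] to the full 513-sample
#' frame (the machine-learning baseline's representation);
#' `featurize_phases()` applies it to the free-fall, impact and rest spans of
#' a [segment_phases()] partition (the multiphase representation).
#'
#' @param frame An `accel_frame`.
#' @param seg A `phase_segmentation` consistent with `frame`; computed when
#'   `NULL`.
#' @param config A [detector_config()].
#' @return `featurize_frame()`: a 54-vector. `featurize_phases()`: a named
#'   list of three 54-vectors (`free_fall`, `impact`, `rest`).
#' @export
featurize_frame <- function(frame, config = detector_config()) {
  frame <- as_frame(frame)
  extract_features(list(ax = frame$ax, ay = frame$ay, az = frame$az), config)
}

#' @rdname featurize_frame
#' @export
featurize_phases <- function(frame, seg = NULL, config = detector_config()) {
  frame <- as_frame(frame)
  if (is.null(seg)) seg <- segment_phases(frame, config)
  lapply(list(free_fall = seg$free_fall, impact = seg$impact,
              rest = seg$rest),
         function(s) extract_features(.slice_frame(frame, s), config))
}
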