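#' Tri-axial accelerometer record
#'
#' Constructs a validated `accel_record`: a continuous tri-axial acceleration
#' time series in units of g (1 g = 9.81 m/s^2) at a fixed sampling rate.
#' This is the raw unit every other stage of the pipeline consumes.
#'
#' @param ax,ay,az Numeric vectors of equal length (>= 1): acceleration along
#'   the x (vertical when standing), y, and z axes, in g.
#' @param sample_rate Sampling frequency in Hz. Default 128.
#' @param t Optional timestamps in seconds. When `NULL` (the usual case) they
#'   are synthesized as `(seq_along(ax) - 1) / sample_rate`; when supplied,
#'   consecutive differences must equal `1/sample_rate` within 1e-9 s.
#' @param label Optional activity label (see [activity_vocabulary()]), or any
#'   free-text tag.
#' @param subject_id Optional subject identifier.
#'
#' @return An object of class `accel_record`: a list with elements
#'   `t`, `ax`, `ay`, `az`, `sample_rate`, `label`, `subject_id`.
#' @examples
#' r <- accel_record(ax = rep(1, 256), ay = rep(0, 256), az = rep(0, 256))
#' length(r)
#' @export
accel_record <- function(ax, ay, az, sample_rate = 128, t = NULL,
                         label = NULL, subject_id = NULL) {
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(ax)
  if (n < 1L)
    stop("accel_record needs at least one sample", call. = FALSE)
  if (length(ay) != n || length(az) != n)
    stop("ax, ay, az must have identical length", call. = FALSE)
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    stop("all accelerations must be finite", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar", call. = FALSE)
  if (is.null(t)) {
    t <- (seq_len(n) - 1) / sample_rate
  } else {
    t <- as.numeric(t)
    if (length(t) != n)
      stop("t must have the same length as the acceleration vectors",
           call. = FALSE)
    if (n > 1L) {
      dt <- diff(t)
      if (any(dt <= 0))
        stop("timestamps must be strictly increasing", call. = FALSE)
      if (any(abs(dt - 1 / sample_rate) > 1e-9))
        stop("non-uniform timestamps: consecutive differences must equal ",
             "1/sample_rate within 1e-9 s", call. = FALSE)
    }
  }
  structure(
    list(t = t, ax = ax, ay = ay, az = az,
         sample_rate = sample_rate,
         label = if (is.null(label)) NULL else as.character(label)[1L],
         subject_id = if (is.null(subject_id)) NULL
                      else as.character(subject_id)[1L]),
    class = "accel_record")
}

#' @export
length.accel_record <- function(x) length(x$ax)

#' @export
print.accel_record <- function(x, ...) {
  cat(sprintf("<accel_record> %d samples @ %g Hz (%.2f s)\n",
              length(x), x$sample_rate, length(x) / x$sample_rate))
  if (!is.null(x$label))
    cat("  label:   ", x$label,
        sprintf(" [%s]", if (is_fall_activity(x$label)) "fall" else "ADL"),
        "\n", sep = "")
  if (!is.null(x$subject_id)) cat("  subject: ", x$subject_id, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.accel_record <- function(x, ...) {
  data.frame(time = x$t, ax = x$ax, ay = x$ay, az = x$az)
}

#' Activity vocabulary
#'
#' The registered fall and ADL activity names used for ground-truth labels:
#' seven fall types (named by the activity being performed when the fall
#' starts) and twelve ADL postures.  `is_fall_activity()` maps a label to its
#' ground-truth class; unknown names are flagged as custom and treated as
#' non-falls with a warning.
#'
#' @return `activity_vocabulary()`: a data.frame with columns `name` and
#'   `is_fall`.
#' @examples
#' activity_vocabulary()
#' is_fall_activity("Walk backward")   # TRUE: a fall type
#' is_fall_activity("Walk (normal)")   # FALSE: an ADL
#' @export
activity_vocabulary <- function() {
  data.frame(
    name = c(
      "Stand", "Stand up", "Sit down", "Stoop", "Walk", "Walk backward",
      "Jump",
      "Stand from sit", "Stand from squat", "Sit (normal)", "Sit (fast)",
      "Lie (normal)", "Lie (fast)", "Go up stairs", "Go down stairs",
      "Walk (normal)", "Walk (fast)", "Jump (ground)", "Jump (bed)"),
    is_fall = rep(c(TRUE, FALSE), c(7L, 12L)),
    stringsAsFactors = FALSE)
}

#' @rdname activity_vocabulary
#' @param name An activity name.
#' @param warn_custom Warn when `name` is not in the registered vocabulary.
#' @export
is_fall_activity <- function(name, warn_custom = FALSE) {
  voc <- activity_vocabulary()
  i <- match(name, voc$name)
  out <- voc$is_fall[i]
  if (anyNA(i)) {
    if (warn_custom)
      warning("custom activity label(s): ",
              paste(unique(name[is.na(i)]), collapse = ", "),
              " (treated as non-fall)", call. = FALSE)
    out[is.na(i)] <- FALSE
  }
  out
}

#' Read and write accelerometer records as CSV
#'
#' The on-disk interchange format is a plain CSV with a header row
#' `time,ax,ay,az` (UTF-8, comma separator, decimal point), accelerations in
#' g.  The `time` column is optional on read: timestamps are regenerated as
#' `(i - 1)/sample_rate` since the algorithm only needs sample indices.
#'
#' @param path File path.
#' @param sample_rate Sampling rate in Hz used to validate/synthesize
#'   timestamps.
#' @param units Either `"g"` (default) or `"ms2"`; m/s^2 input is divided by
#'   9.81 on read.
#' @param label,subject_id Optional metadata attached to the returned record
#'   (normally supplied by the manifest, see [read_manifest()]).
#' @return `read_record()`: an [accel_record()]. `write_record()`: `path`,
#'   invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' r <- accel_record(ax = rnorm(16, 1, .1), ay = rnorm(16, 0, .1),
#'                   az = rnorm(16, 0, .1))
#' write_record(r, p)
#' r2 <- read_record(p)
#' max(abs(r2$ax - r$ax)) < 1e-12
#' @export
read_record <- function(path, sample_rate = 128, units = c("g", "ms2"),
                        label = NULL, subject_id = NULL) {
  units <- match.arg(units)
  if (!file.exists(path))
    stop("record file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, strip.white = TRUE),
    error = function(e)
      stop("malformed CSV at ", path, ": ", conditionMessage(e),
           call. = FALSE))
  need <- c("ax", "ay", "az")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), " (header line 1)", call. = FALSE)
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop("parse error in ", path, ": non-numeric ", col,
           " at data line ", bad, call. = FALSE)
    }
  }
  scl <- if (units == "ms2") 1 / 9.81 else 1
  t <- if ("time" %in% names(df)) as.numeric(df$time) else NULL
  accel_record(ax = df$ax * scl, ay = df$ay * scl, az = df$az * scl,
               sample_rate = sample_rate, t = t,
               label = label, subject_id = subject_id)
}

#' @rdname read_record
#' @param record An [accel_record()].
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "accel_record"))
  df <- as.data.frame(record)
  # %.17g preserves doubles exactly through the round trip
  lines <- c("time,ax,ay,az",
             sprintf("%.17g,%.17g,%.17g,%.17g", df$time, df$ax, df$ay, df$az))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write record to ", path, call. = FALSE)
  invisible(path)
}

#' Read and write dataset manifests
#'
#' A manifest is a CSV with columns `path,label,subject`, one row per record
#' file; ground truth lives here rather than inside the signal files so one
#' record format serves labeled and unlabeled data.  Relative record paths
#' are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @param check_exists Error if a referenced record file is missing
#'   (default `TRUE`).
#' @return A data.frame with columns `path`, `label`, `subject`, `is_fall`,
#'   `custom` (label not in the registered vocabulary), in file order.
#' @export
read_manifest <- function(path, check_exists = TRUE) {
  if (!file.exists(path))
    stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, strip.white = TRUE,
                        colClasses = "character")
  if (nrow(df) == 0L)
    return(data.frame(path = character(), label = character(),
                      subject = character(), is_fall = logical(),
                      custom = logical(), stringsAsFactors = FALSE))
  if (!all(c("path", "label") %in% names(df)))
    stop("manifest must have columns path,label[,subject]", call. = FALSE)
  if (is.null(df$subject)) df$subject <- NA_character_
  full <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                 file.path(dirname(path), df$path))
  if (check_exists) {
    gone <- full[!file.exists(full)]
    if (length(gone))
      stop("record file(s) listed in manifest not found: ",
           paste(gone, collapse = ", "), call. = FALSE)
  }
  voc <- activity_vocabulary()
  custom <- !(df$label %in% voc$name)
  if (any(custom))
    warning("unknown activity name(s) flagged custom: ",
            paste(unique(df$label[custom]), collapse = ", "), call. = FALSE)
  data.frame(path = full, label = df$label, subject = df$subject,
             is_fall = is_fall_activity(df$label), custom = custom,
             stringsAsFactors = FALSE)
}

#' @rdname read_manifest
#' @param entries Data.frame with columns `path`, `label` and optionally
#'   `subject`.
#' @export
write_manifest <- function(entries, path) {
  stopifnot(is.data.frame(entries))
  if (is.null(entries$subject)) entries$subject <- rep("", nrow(entries))
  utils::write.csv(entries[, c("path", "label", "subject")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}
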