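#' Simulator configuration
#'
#' Parameters of the synthetic accelerometer generator.  Defaults emulate a
#' waist-worn sensor at 128 Hz: a fall consists of pre-fall activity, a
#' free-fall interval in which the norm drops toward 0 g (duration drawn
#' from 0.12–0.8 s, the range reported for instrumented falls), a sharp
#' sub-second impact pulse whose peak sets the severity, a damped settling
#' transient, and a motionless rest at 1 g in the post-fall orientation.
#'
#' @param sample_rate Sampling rate in Hz (default 128).
#' @param pre_fall_duration Seconds of pre-fall activity (default 2 s, so
#'   the 192-sample look-back window is fully populated without padding).
#' @param free_fall_duration Seconds of free fall; `NULL` (default) draws
#'   uniformly from 0.12–0.8 s per record.
#' @param impact_peak Peak impact norm in g; `NULL` (default) draws
#'   uniformly from 3–8 g, straddling the 6 g severity boundary.
#' @param impact_duration Impact pulse width in seconds (< 1 s; default
#'   0.16 s, i.e. a 21-sample half-sine at 128 Hz).
#' @param rest_duration Seconds of post-impact signal (default 3 s, so the
#'   320-sample look-ahead window is fully populated).
#' @param noise_sd Gaussian sensor noise standard deviation in g
#'   (default 0.05).
#' @param orientation Unit 3-vector of the static gravity component while
#'   upright (default `c(1, 0, 0)`: x vertical).
#' @param seed Optional integer; when set, generation is bit-reproducible
#'   and the global RNG state is left untouched.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 128, pre_fall_duration = 2,
                       free_fall_duration = NULL, impact_peak = NULL,
                       impact_duration = 0.16, rest_duration = 3,
                       noise_sd = 0.05, orientation = c(1, 0, 0),
                       seed = NULL) {
  stopifnot(sample_rate > 0, pre_fall_duration > 0,
            impact_duration > 0, impact_duration < 1,
            rest_duration > 0, noise_sd >= 0, length(orientation) == 3L)
  if (!is.null(free_fall_duration)) stopifnot(free_fall_duration > 0)
  if (!is.null(impact_peak)) stopifnot(impact_peak > 0)
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(sample_rate = sample_rate,
                 pre_fall_duration = pre_fall_duration,
                 free_fall_duration = free_fall_duration,
                 impact_peak = impact_peak,
                 impact_duration = impact_duration,
                 rest_duration = rest_duration,
                 noise_sd = noise_sd, orientation = orientation,
                 seed = seed),
            class = "sim_config")
}

# evaluate expr under an isolated RNG stream when seed is non-NULL
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.unit <- function(v) v / sqrt(sum(v^2))

# tri-axial gait: vertical oscillation at the step frequency plus a weaker
# harmonic and small lateral sway, riding on static gravity
.gait <- function(n, fs, orient, amp, freq, noise_sd) {
  t <- (seq_len(n) - 1) / fs
  vert <- 1 + amp * sin(2 * pi * freq * t) +
    0.35 * amp * sin(4 * pi * freq * t + 0.7)
  sway <- 0.25 * amp * sin(2 * pi * freq * t + 1.3)
  base <- outer(vert, orient)
  lat <- .unit(if (abs(orient[2L]) < 0.9) c(0, 1, 0) else c(0, 0, 1))
  base + outer(sway, lat) + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3L)
}

.quiet <- function(n, fs, orient, noise_sd) {
  outer(rep(1, n), orient) + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3L)
}

# smooth half-sine bump of given peak (g) and width (samples) along dir
.bump <- function(n, peak, dir) {
  outer(peak * sin(pi * seq_len(n) / (n + 1)), .unit(dir))
}

#' Simulate a fall record
#'
#' Generates one labeled fall: pre-fall activity appropriate to the fall
#' type (gait for walking falls, quiet standing otherwise), a free-fall
#' interval in which the norm decays below 0.5 g, a half-sine impact pulse
#' peaking at `impact_peak`, a damped settling oscillation, and motionless
#' rest in a lying orientation.  Per-sample phase ground truth is returned
#' alongside the record.
#'
#' @param config A [sim_config()].
#' @param fall_type One of the seven fall activity names (see
#'   [activity_vocabulary()]).
#' @param subject_id Optional subject tag.
#' @return A list of class `annotated_record` with `record` (an
#'   [accel_record()], labeled) and `phases` (character, one of `PreFall`,
#'   `FreeFall`, `Impact`, `Rest` per sample).
#' @examples
#' ar <- gen_fall(sim_config(impact_peak = 7, seed = 42))
#' max(compute_norms(ar$record)$norm_xyz)  # ~7 g
#' @export
gen_fall <- function(config = sim_config(), fall_type = "Stand",
                     subject_id = NULL) {
  falls <- activity_vocabulary()
  falls <- falls$name[falls$is_fall]
  if (!fall_type %in% falls)
    stop("unknown fall type: ", fall_type, call. = FALSE)
  .with_seed(config$seed, {
    fs <- config$sample_rate
    d_ff <- if (is.null(config$free_fall_duration))
      stats::runif(1, 0.12, 0.8) else config$free_fall_duration
    peak <- if (is.null(config$impact_peak))
      stats::runif(1, 3, 8) else config$impact_peak
    n_pre <- round(config$pre_fall_duration * fs)
    n_ff <- max(4L, round(d_ff * fs))
    n_imp <- round(config$impact_duration * fs)
    if (n_imp %% 2L == 0L) n_imp <- n_imp + 1L  # odd: single peak sample
    n_rest <- round(config$rest_duration * fs)

    pre <- switch(fall_type,
      "Walk" = ,
      "Walk backward" = .gait(n_pre, fs, config$orientation, 0.3, 2,
                              config$noise_sd),
      "Jump" = {
        q <- .quiet(n_pre, fs, config$orientation, config$noise_sd)
        nb <- min(round(0.12 * fs), n_pre)
        q[seq_len(nb), ] <- q[seq_len(nb), ] + .bump(nb, 1.2, c(1, 0.2, 0.1))
        q
      },
      .quiet(n_pre, fs, config$orientation, config$noise_sd))

    # free fall: the gravity-tracked component collapses toward 0 g
    tf <- seq_len(n_ff) / n_ff
    fac <- 0.05 + 0.95 * (1 - tf)^8
    ff <- outer(fac, config$orientation) +
      matrix(stats::rnorm(3 * n_ff, 0, config$noise_sd / 2), n_ff, 3L)

    # impact: half-sine pulse along a random direction
    u <- .unit(stats::rnorm(3))
    imp <- .bump(n_imp, peak, u) +
      matrix(stats::rnorm(3 * n_imp, 0, config$noise_sd / 4), n_imp, 3L)

    # settle + rest: lying orientation (gravity moved off the x axis)
    side <- sample(c(2L, 3L), 1L)
    o2 <- .unit(replace(c(0.15, 0, 0), side, sample(c(-1, 1), 1L)))
    tr <- (seq_len(n_rest) - 1) / fs
    osc <- 0.6 * exp(-tr / 0.35) * sin(2 * pi * 6 * tr)
    rest <- outer(1 + osc, o2) +
      matrix(stats::rnorm(3 * n_rest, 0, config$noise_sd), n_rest, 3L)

    sig <- rbind(pre, ff, imp, rest)
    phases <- rep(c("PreFall", "FreeFall", "Impact", "Rest"),
                  c(n_pre, n_ff, n_imp, n_rest))
    rec <- accel_record(ax = sig[, 1L], ay = sig[, 2L], az = sig[, 3L],
                        sample_rate = fs, label = fall_type,
                        subject_id = subject_id)
    structure(list(record = rec, phases = phases),
              class = "annotated_record")
  })
}

#' Simulate an ADL record
#'
#' Generates one labeled activity of daily living: periodic ~2 Hz gait for
#' walking and stair archetypes, a single moderate transient for
#' sit/stand/lie transitions (with the fast lying variants reaching 2.5–4 g
#' to mimic the hardest, most fall-like ADLs), and repeated moderate spikes
#' for jumping.  No free-fall interval is generated and no `FreeFall`
#' annotation ever appears.
#'
#' @param config A [sim_config()].
#' @param adl_type One of the twelve ADL names (see
#'   [activity_vocabulary()]).
#' @param subject_id Optional subject tag.
#' @return An `annotated_record`; `phases` are all `"None"`.
#' @export
gen_adl <- function(config = sim_config(), adl_type = "Walk (normal)",
                    subject_id = NULL) {
  voc <- activity_vocabulary()
  if (!adl_type %in% voc$name[!voc$is_fall])
    stop("unknown ADL archetype: ", adl_type, call. = FALSE)
  .with_seed(config$seed, {
    fs <- config$sample_rate
    ns <- config$noise_sd
    orient <- config$orientation
    n_pre <- round(config$pre_fall_duration * fs)
    n_tail <- round(config$rest_duration * fs)

    gait_spec <- list("Walk (normal)" = c(0.30, 2.0),
                      "Walk (fast)" = c(0.50, 2.5),
                      "Go up stairs" = c(0.35, 1.8),
                      "Go down stairs" = c(0.45, 2.0))
    if (adl_type %in% names(gait_spec)) {
      gs <- gait_spec[[adl_type]]
      n <- n_pre + round(1 * fs) + n_tail
      sig <- .gait(n, fs, orient, gs[1L], gs[2L], ns)
    } else if (adl_type %in% c("Jump (ground)", "Jump (bed)")) {
      # rhythmic jumping: repeated takeoff-push / flight / landing cycles.
      # Later landings taper off (fatigue), so the loudest landing falls
      # early in the bout and jumping continues through its look-ahead
      # window — a jumper does not freeze motionless after a landing.
      amp <- if (adl_type == "Jump (ground)") stats::runif(1, 1.8, 3.0)
             else stats::runif(1, 1.2, 2.2)
      ncyc <- 7L
      taper <- seq(1, 0.65, length.out = ncyc)
      n_push <- round(0.10 * fs); n_fly <- round(0.20 * fs)
      n_land <- round(0.12 * fs); n_gap <- round(0.12 * fs)
      segs <- list(.quiet(n_pre, fs, orient, ns))
      for (cc in seq_len(ncyc)) {
        push <- .quiet(n_push, fs, orient, ns) +
          .bump(n_push, 0.8 * stats::runif(1, 0.8, 1.2), c(1, 0.2, 0.1))
        fac <- 0.25 + 0.1 * stats::runif(n_fly)
        fly <- outer(fac, orient) +
          matrix(stats::rnorm(3 * n_fly, 0, ns), n_fly, 3L)
        land <- .quiet(n_land, fs, orient, ns) +
          .bump(n_land, amp * taper[cc] * stats::runif(1, 0.75, 1),
                c(1, 0.25, 0.15))
        segs <- c(segs, list(push, fly, land,
                             .quiet(n_gap, fs, orient, ns)))
      }
      segs <- c(segs, list(.quiet(n_tail, fs, orient, ns)))
      sig <- do.call(rbind, segs)
      n <- nrow(sig)
    } else {
      # single-transient archetypes: sit / stand / lie
      spec <- switch(adl_type,
        "Stand from sit" = list(a = c(0.5, 1.0), w = 0.5, lie = FALSE),
        "Stand from squat" = list(a = c(0.6, 1.1), w = 0.5, lie = FALSE),
        "Sit (normal)" = list(a = c(0.5, 1.0), w = 0.6, lie = FALSE),
        "Sit (fast)" = list(a = c(1.0, 1.8), w = 0.3, lie = FALSE),
        "Lie (normal)" = list(a = c(0.8, 1.6), w = 0.6, lie = TRUE),
        "Lie (fast)" = list(a = c(1.5, 3.0), w = 0.3, lie = TRUE))
      amp <- stats::runif(1, spec$a[1L], spec$a[2L])
      nb <- round(spec$w * fs)
      n_mid <- max(nb + round(0.5 * fs), round(1.5 * fs))
      n <- n_pre + n_mid + n_tail
      if (spec$lie) {
        # orientation rotates from upright to lying across the transient
        side <- sample(c(2L, 3L), 1L)
        o2 <- .unit(replace(c(0.15, 0, 0), side, sample(c(-1, 1), 1L)))
        w01 <- stats::plogis(seq(-6, 6, length.out = n),
                             scale = spec$w * 1.5)
        mix <- outer(1 - w01, orient) + outer(w01, o2)
        mix <- mix / sqrt(rowSums(mix^2))
        sig <- mix + matrix(stats::rnorm(3 * n, 0, ns), n, 3L)
      } else {
        sig <- .quiet(n, fs, orient, ns)
      }
      idx <- n_pre + seq_len(nb)
      dir <- c(1, stats::runif(1, 0.1, 0.5), stats::runif(1, 0.1, 0.5))
      sig[idx, ] <- sig[idx, ] + .bump(nb, amp, dir)
    }
    rec <- accel_record(ax = sig[, 1L], ay = sig[, 2L], az = sig[, 3L],
                        sample_rate = fs, label = adl_type,
                        subject_id = subject_id)
    structure(list(record = rec, phases = rep("None", n)),
              class = "annotated_record")
  })
}

#' @export
print.annotated_record <- function(x, ...) {
  cat("<annotated_record>\n")
  print(x$record)
  ph <- rle(x$phases)
  cat("  phases: ", paste(sprintf("%s(%d)", ph$values, ph$lengths),
                          collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Generate a labeled mixed dataset
#'
#' Produces a reproducible mix of fall and ADL records, cycling through all
#' seven fall types and all twelve ADL archetypes, with fall severities
#' drawn from `severity_range` (covering both sides of the 6 g boundary by
#' default) and subjects cycled `S1`..`S8`.
#'
#' @param n_falls,n_adls Record counts (>= 0).
#' @param severity_range Range of impact peaks in g falls are drawn from
#'   (default `c(3, 8)`).
#' @param seed Integer seed; the dataset is bit-reproducible given the seed.
#' @param config Base [sim_config()]; per-record durations/peaks are drawn
#'   from it.
#' @return A list of `annotated_record`s of length `n_falls + n_adls`.
#' @export
gen_dataset <- function(n_falls = 25, n_adls = 25, severity_range = c(3, 8),
                        seed = 1, config = sim_config()) {
  stopifnot(n_falls >= 0, n_adls >= 0, length(severity_range) == 2L)
  voc <- activity_vocabulary()
  fall_types <- voc$name[voc$is_fall]
  adl_types <- voc$name[!voc$is_fall]
  per_rec <- config
  per_rec$seed <- NULL
  .with_seed(seed, {
    out <- vector("list", n_falls + n_adls)
    for (i in seq_len(n_falls)) {
      cfg <- per_rec
      cfg$impact_peak <- stats::runif(1, severity_range[1L],
                                      severity_range[2L])
      out[[i]] <- gen_fall(cfg, fall_types[(i - 1L) %% 7L + 1L],
                           subject_id = paste0("S", (i - 1L) %% 8L + 1L))
    }
    for (j in seq_len(n_adls)) {
      out[[n_falls + j]] <- gen_adl(per_rec,
                                    adl_types[(j - 1L) %% 12L + 1L],
                                    subject_id = paste0("S", (j - 1L) %% 8L + 1L))
    }
    out
  })
}

#' Write a generated dataset to disk
#'
#' Emits the interchange formats of [read_record()]/[read_manifest()]: one
#' CSV per record under `records/`, a `manifest.csv`, and per-sample phase
#' annotations (`index,phase`) under `annotations/`.
#'
#' @param dataset A list of `annotated_record`s from [gen_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(file.path(out_dir, "records"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  n <- length(dataset)
  rel <- sprintf("records/rec_%04d.csv", seq_len(n))
  for (i in seq_len(n)) {
    ar <- dataset[[i]]
    write_record(ar$record, file.path(out_dir, rel[i]))
    utils::write.csv(
      data.frame(index = seq_along(ar$phases), phase = ar$phases),
      file.path(out_dir, sprintf("annotations/rec_%04d_phases.csv", i)),
      row.names = FALSE, quote = FALSE)
  }
  entries <- data.frame(
    path = rel,
    label = vapply(dataset, function(a)
      if (is.null(a$record$label)) "" else a$record$label, character(1)),
    subject = vapply(dataset, function(a)
      if (is.null(a$record$subject_id)) "" else a$record$subject_id,
      character(1)),
    stringsAsFactors = FALSE)
  write_manifest(entries, file.path(out_dir, "manifest.csv"))
  invisible(file.path(out_dir, "manifest.csv"))
}
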