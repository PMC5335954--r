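# Independent direct-formula oracle for the 54 time-domain features.
# Deliberately written from the defining formulas (explicit sums, sorted
# order statistics), not by calling the package's extraction path.
oracle_features <- function(ax, ay, az, vert_pair = "xy") {
  m <- length(ax)
  a_norm <- sqrt(ax^2 + ay^2 + az^2)
  a_verti <- if (vert_pair == "xy") sqrt(ax^2 + ay^2) else sqrt(ax^2 + az^2)
  a_hori <- sqrt(ay^2 + az^2)
  sigs <- list(ax, ay, az, a_norm, a_verti, a_hori)

  o_mean <- function(x) sum(x) / m
  cmom <- function(x, k) sum((x - o_mean(x))^k) / m
  o_sd <- function(x) sqrt(sum((x - o_mean(x))^2) / (m - 1))
  o_var <- function(x) sum((x - o_mean(x))^2) / (m - 1)
  o_max <- function(x) sort(x)[m]
  o_min <- function(x) sort(x)[1L]
  o_kurt <- function(x) {
    m2 <- cmom(x, 2)
    if (m2 == 0) 0 else cmom(x, 4) / m2^2
  }
  o_skew <- function(x) {
    m2 <- cmom(x, 2)
    if (m2 == 0) 0 else cmom(x, 3) / m2^1.5
  }
  o_cor <- function(x, y) {
    sx <- sqrt(cmom(x, 2)); sy <- sqrt(cmom(y, 2))
    if (sx == 0 || sy == 0) return(0)
    sum((x - o_mean(x)) * (y - o_mean(y))) / (m * sx * sy)
  }
  c(sapply(sigs, o_mean), sapply(sigs, o_sd), sapply(sigs, o_var),
    sapply(sigs, o_max), sapply(sigs, o_min),
    sapply(sigs, function(x) o_max(x) - o_min(x)),
    sapply(sigs, o_kurt), sapply(sigs, o_skew),
    o_cor(ax, ay), o_cor(ax, az), o_cor(ay, az),
    o_cor(a_norm, a_verti), o_cor(a_norm, a_hori),
    o_cor(a_verti, a_hori))
}

# a 513-sample frame that is quiet at `base` g on x with a single
# tri-axial spike at the critical position (local index 193)
spike_frame <- function(spike = c(0, 3, 4), base = 1) {
  ax <- rep(base, 513); ay <- rep(0, 513); az <- rep(0, 513)
  ax[193] <- spike[1]; ay[193] <- spike[2]; az[193] <- spike[3]
  rec <- accel_record(ax = ax, ay = ay, az = az)
  make_frame(rec, find_critical_point(compute_norms(rec)))
}

# small labeled dataset for classifier/evaluation tests
small_dataset <- function(n_falls, n_adls, seed, ...) {
  gen_dataset(n_falls, n_adls, seed = seed, ...)
}

dataset_labels <- function(ds)
  vapply(ds, function(a) a$record$label, character(1))
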