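test_that("phase spans follow the severity rule and tile the frame tail", {
  severe <- spike_frame(spike = c(0, 0, 7))
  s <- segment_phases(severe)
  expect_equal(s$situation, "severe")
  expect_equal(s$impact, c(183, 203))      # 10 + critical + 10 = 21
  expect_equal(s$free_fall, c(151, 182))   # the 32 samples before impact
  expect_equal(s$rest, c(204, 513))
  expect_equal(diff(s$impact) + 1, 21)
  expect_equal(diff(s$rest) + 1, 310)

  mild <- spike_frame(spike = c(0, 0, 5))
  m <- segment_phases(mild)
  expect_equal(m$situation, "mild")
  expect_equal(m$impact, c(183, 213))      # 10 + critical + 20 = 31
  expect_equal(m$free_fall, c(151, 182))
  expect_equal(m$rest, c(214, 513))
  expect_equal(diff(m$rest) + 1, 300)

  # a peak exactly at 6 g is assigned to the severe (saturation) branch
  expect_equal(segment_phases(spike_frame(spike = c(6, 0, 0)))$situation,
               "severe")

  # spans are contiguous, ordered, non-overlapping for random frames
  set.seed(9)
  for (i in 1:10) {
    f <- as_frame(gen_fall(sim_config(), "Stoop"))
    sg <- segment_phases(f)
    expect_equal(diff(sg$free_fall) + 1, 32)
    expect_equal(sg$impact[1], sg$free_fall[2] + 1)
    expect_equal(sg$rest[1], sg$impact[2] + 1)
    expect_equal(sg$rest[2], 513)
    expect_true(sg$situation %in% c("severe", "mild"))
    expect_equal(diff(sg$impact) + 1,
                 if (sg$situation == "severe") 21 else 31)
  }
})

test_that("feature extraction handles the stated base cases", {
  const <- list(ax = rep(1, 10), ay = rep(0, 10), az = rep(0, 10))
  fv <- extract_features(const)
  expect_length(fv, 54L)
  expect_named(fv, paste0("f", 1:54))
  expect_equal(unname(fv["f1"]), 1)   # mean ax
  expect_equal(unname(fv["f7"]), 0)   # std ax
  expect_equal(unname(fv["f31"]), 0)  # range ax
  expect_true(all(fv[paste0("f", 49:54)] == 0))  # degenerate correlations

  ramp <- list(ax = c(1, 2, 3), ay = c(0, 0, 0), az = c(0, 0, 0))
  fr <- extract_features(ramp)
  expect_equal(unname(fr["f19"]), 3)  # max ax
  expect_equal(unname(fr["f25"]), 1)  # min ax
  expect_equal(unname(fr["f31"]), 2)  # range ax
  expect_equal(unname(fr["f7"]), 1)   # sample (n-1) std of 1,2,3
  expect_equal(unname(fr["f13"]), 1)  # sample variance

  expect_error(extract_features(list(ax = 1, ay = 1, az = 1)),
               "too short")
})

test_that("every feature matches the direct-formula oracle", {
  set.seed(5)
  for (i in 1:50) {
    m <- sample(5:60, 1)
    ax <- rnorm(m, 1, 0.8); ay <- rnorm(m, 0, 0.8); az <- rnorm(m, 0, 0.8)
    got <- extract_features(list(ax = ax, ay = ay, az = az))
    want <- oracle_features(ax, ay, az)
    expect_lt(max(abs(got - want)), 1e-9)
    expect_true(all(abs(got[paste0("f", 49:54)]) <= 1 + 1e-12))
    # internal consistency: range = max - min, var = std^2
    expect_lt(max(abs(got[31:36] - (got[19:24] - got[25:30]))), 1e-12)
    expect_lt(max(abs(got[13:18] - got[7:12]^2)), 1e-9)
  }
})

test_that("estimator conventions are switchable", {
  x <- list(ax = c(1, 2, 3, 7), ay = c(0, 1, 0, 2), az = c(1, 1, 2, 0))
  pop <- extract_features(x, detector_config(sd_denom = "n", var_denom = "n"))
  expect_equal(unname(pop["f13"]), mean((x$ax - mean(x$ax))^2))
  exc <- extract_features(x, detector_config(kurt_form = "excess"))
  std <- extract_features(x)
  expect_equal(unname(exc["f37"]), unname(std["f37"]) - 3)
  adj <- extract_features(x, detector_config(skew_form = "G1"))
  n <- 4
  expect_equal(unname(adj["f43"]),
               unname(std["f43"]) * sqrt(n * (n - 1)) / (n - 2))
})

test_that("frame and phase featurization use the right segment sizes", {
  z <- accel_record(ax = rep(0, 513), ay = rep(0, 513), az = rep(0, 513))
  zf <- make_frame(z)
  fv <- featurize_frame(zf)
  expect_true(all(fv[1:18] == 0))  # zero frame: all means and spreads 0
  expect_equal(attr(fv, "m"), 513L)

  severe <- spike_frame(spike = c(0, 0, 7))
  expect_equal(unname(featurize_frame(severe)["f22"]), 7)  # max a_norm
  ph <- featurize_phases(severe)
  expect_named(ph, c("free_fall", "impact", "rest"))
  expect_equal(attr(ph$impact, "m"), 21L)
  expect_equal(attr(ph$free_fall, "m"), 32L)
  expect_equal(attr(ph$rest, "m"), 310L)

  mild <- spike_frame(spike = c(0, 0, 5))
  phm <- featurize_phases(mild)
  expect_equal(attr(phm$impact, "m"), 31L)
  expect_equal(attr(phm$rest, "m"), 300L)
  expect_true(all(vapply(ph, length, integer(1)) == 54L))
})
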