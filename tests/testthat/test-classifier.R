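make_fit <- function(n_falls = 14, n_adls = 14, seed = 1) {
  ds <- small_dataset(n_falls, n_adls, seed)
  list(ds = ds, fit = fall_detector(ds))
}

test_that("the phase machine is a 3-class one-vs-one linear SVM", {
  w <- make_fit()
  expect_s3_class(w$fit, "fall_detector")
  expect_equal(length(w$fit$svm$levels), 3L)
  # one-vs-one: x(x-1)/2 = 3 binary classifiers behind a 3-class machine
  expect_equal(length(w$fit$svm$rho), 3L)
  expect_equal(w$fit$svm$kernel, 0L)  # linear
})

test_that("separable severe falls are phase-classified perfectly in training", {
  # fixed long free fall and high peak make the three phases linearly
  # separable by construction
  cfg <- sim_config(free_fall_duration = 0.4, impact_peak = 7)
  set.seed(1)
  falls <- replicate(10, gen_fall(cfg, "Stand"), simplify = FALSE)
  adls <- replicate(4, gen_adl(sim_config(), "Walk (normal)"),
                    simplify = FALSE)
  fit <- fall_detector(c(falls, adls))
  for (f in falls) {
    pp <- predict_phases(fit, as_frame(f))
    expect_equal(pp$phase, c("FreeFall", "Impact", "Rest"))
    expect_true(all(diff(pp$time) > 0))
  }
})

test_that("refitting with identical data and seed reproduces predictions", {
  ds <- small_dataset(10, 10, seed = 3)
  probe <- as_frame(gen_fall(sim_config(impact_peak = 4, seed = 99)))
  f1 <- fall_detector(ds)
  f2 <- fall_detector(ds)
  expect_identical(predict_phases(f1, probe)$phase,
                   predict_phases(f2, probe)$phase)
  expect_identical(predict(f1, ds), predict(f2, ds))
})

test_that("the temporal-order rule accepts exactly one of 27 sequences", {
  phases <- c("FreeFall", "Impact", "Rest")
  grid <- expand.grid(a = phases, b = phases, c = phases,
                      stringsAsFactors = FALSE)
  ok <- apply(grid, 1, function(s) check_temporal_order(unname(s)))
  expect_equal(sum(ok), 1L)
  expect_true(check_temporal_order(c("FreeFall", "Impact", "Rest")))
  expect_false(check_temporal_order(c("Impact", "FreeFall", "Rest")))
  expect_false(check_temporal_order(c("FreeFall", "FreeFall", "Rest")))
})

test_that("detection routes through the hierarchy and short-circuits", {
  w <- make_fit(20, 20, seed = 6)
  th <- w$fit$thresholds
  pr <- predict(w$fit, w$ds)
  # threshold-stage rows carry no phase prediction; knowledge rows do
  expect_true(all(is.na(pr$phases[pr$stage == "threshold"])))
  expect_true(all(!is.na(pr$phases[pr$stage == "knowledge"])))
  # rows above both fall thresholds short-circuit to Fall at triage
  hi <- pr$v > th$t_fall_xyz & pr$w > th$t_fall_hori
  expect_true(all(pr$stage[hi] == "threshold" & pr$decision[hi] == "Fall"))
  lo <- pr$v < th$t_adl_xyz & pr$w < th$t_adl_hori
  expect_true(all(pr$stage[lo] == "threshold" & pr$decision[lo] == "ADL"))
  # everything else went to the knowledge stage
  expect_true(all(pr$stage[!hi & !lo] == "knowledge"))

  # a single detect() call agrees with the tabulated prediction
  d1 <- detect(w$ds[[1]], w$fit)
  expect_s3_class(d1, "fall_decision")
  expect_equal(d1$decision, pr$decision[1])
  expect_equal(d1$stage, pr$stage[1])
})

test_that("ambiguous falls are recovered by the knowledge stage", {
  w <- make_fit(30, 30, seed = 8)
  labs <- dataset_labels(w$ds)
  pr <- predict(w$fit, w$ds)
  isf <- is_fall_activity(labs)
  kn_falls <- pr$stage == "knowledge" & isf
  # the generator's severity mix straddles the threshold band, so some
  # falls must be deferred to the knowledge stage ...
  expect_gt(sum(kn_falls), 0L)
  # ... and the phase-order rule recovers nearly all of them
  expect_gte(mean(pr$decision[kn_falls] == "Fall"), 0.9)
  ordered <- !is.na(pr$phases) & pr$phases == "FreeFall>Impact>Rest"
  expect_equal(pr$decision[pr$stage == "knowledge"],
               ifelse(ordered[pr$stage == "knowledge"], "Fall", "ADL"))
})

test_that("model bundles persist and reload without behavior change", {
  w <- make_fit(10, 10, seed = 4)
  p <- tempfile(fileext = ".rds")
  save_detector(w$fit, p)
  back <- load_detector(p)
  expect_identical(predict(back, w$ds), predict(w$fit, w$ds))
  expect_error(load_detector({
    q <- tempfile(); saveRDS(1:3, q); q
  }), "bundle")
})

test_that("the whole-frame baseline trains, predicts, and enforces contracts", {
  ds <- small_dataset(16, 16, seed = 5)
  base <- frame_classifier(ds)
  pred <- predict(base, ds)
  expect_true(all(pred %in% c("Fall", "ADL")))
  # separable-by-construction training set is fit perfectly
  isf <- is_fall_activity(dataset_labels(ds))
  expect_gte(mean((pred == "Fall") == isf), 0.95)
  # determinism
  expect_identical(predict(frame_classifier(ds), ds), pred)
  # single-class input is a fitting error
  expect_error(frame_classifier(ds[isf]), "both classes")
  # malformed feature matrices are rejected
  expect_error(phasefall:::.feature_matrix(list(rep(0, 10))), "54")
})
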