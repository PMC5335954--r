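test_that("frame extrema are the maxima of the two norm series", {
  f <- spike_frame(spike = c(0, 3, 4), base = 1)
  ex <- frame_extrema(f)
  expect_equal(ex$v, 5)
  expect_equal(ex$w, 5)

  const <- accel_record(ax = rep(1, 513), ay = rep(0, 513),
                        az = rep(0, 513))
  exc <- frame_extrema(make_frame(const))
  expect_equal(exc$v, 1)
  expect_equal(exc$w, 0)

  set.seed(3)
  r <- accel_record(ax = rnorm(513), ay = rnorm(513), az = rnorm(513))
  fr <- make_frame(r)
  exr <- frame_extrema(fr)
  brute <- apply(cbind(fr$ax, fr$ay, fr$az), 1, function(s)
    sqrt(sum(s^2)))
  expect_equal(exr$v, max(brute))
  expect_equal(exr$w, max(sqrt(fr$ay^2 + fr$az^2)))
  expect_gte(exr$v, exr$w)
})

test_that("thresholds equal the class extrema of the training set", {
  ex <- data.frame(v = c(4, 5, 2, 2.5), w = c(3.5, 4.5, 1.5, 2))
  th <- fit_thresholds(ex, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(th$t_fall_xyz, 2.5)   # max ADL v
  expect_equal(th$t_fall_hori, 2)    # max ADL w
  expect_equal(th$t_adl_xyz, 4)      # min fall v
  expect_equal(th$t_adl_hori, 3.5)   # min fall w

  one <- fit_thresholds(data.frame(v = c(5, 2), w = c(4, 1)),
                        c(TRUE, FALSE))
  expect_equal(unlist(unclass(one)),
               c(t_fall_xyz = 2, t_fall_hori = 1, t_adl_xyz = 5,
                 t_adl_hori = 4))

  expect_error(fit_thresholds(data.frame(v = 1, w = 1), TRUE), "ADL")
  expect_error(fit_thresholds(data.frame(v = 1, w = 1), FALSE), "fall")

  # brute force on 100 simulated extrema
  set.seed(11)
  v <- runif(100, 1, 8); w <- v * runif(100, 0.2, 1)
  isf <- runif(100) < 0.5
  th2 <- fit_thresholds(data.frame(v = v, w = w), isf)
  expect_equal(th2$t_fall_xyz, max(v[!isf]))
  expect_equal(th2$t_fall_hori, max(w[!isf]))
  expect_equal(th2$t_adl_xyz, min(v[isf]))
  expect_equal(th2$t_adl_hori, min(w[isf]))
})

test_that("triage follows the three-branch rule with strict inequalities", {
  th <- fit_thresholds(data.frame(v = c(5, 2), w = c(4, 1)),
                       c(TRUE, FALSE))
  # t_fall = (2, 1), t_adl = (5, 4)
  expect_equal(triage(list(v = 6, w = 5), th), "Fall")
  expect_equal(triage(list(v = 1, w = 0.5), th), "ADL")
  expect_equal(triage(list(v = 6, w = 0.5), th), "Unidentified")
  # boundary values are deferred, not classified (strict inequalities)
  expect_equal(triage(list(v = 2, w = 5), th), "Unidentified")
  expect_equal(triage(list(v = 5, w = 0.5), th), "Unidentified")
})

test_that("triage partitions, stays consistent on training data, and is monotone", {
  set.seed(21)
  v <- runif(200, 1, 8); w <- v * runif(200, 0.2, 1)
  isf <- v + w + rnorm(200) > 6  # overlapping classes
  if (!any(isf)) isf[1] <- TRUE
  if (all(isf)) isf[2] <- FALSE
  th <- fit_thresholds(data.frame(v = v, w = w), isf)
  labels <- mapply(function(vi, wi) triage(list(v = vi, w = wi), th), v, w)
  # partition: every frame gets exactly one of the three labels
  expect_true(all(labels %in% c("Fall", "ADL", "Unidentified")))
  # consistency: no training ADL is triaged Fall, no training fall ADL
  expect_false(any(labels == "Fall" & !isf))
  expect_false(any(labels == "ADL" & isf))
  # monotonicity: raising (v, w) never moves a label toward ADL
  rank <- c(ADL = 1, Unidentified = 2, Fall = 3)
  for (i in 1:100) {
    vi <- runif(1, 1, 8); wi <- vi * runif(1, 0.2, 1)
    dv <- runif(1, 0, 2); dw <- runif(1, 0, 2)
    expect_gte(rank[triage(list(v = vi + dv, w = wi + dw), th)],
               rank[triage(list(v = vi, w = wi), th)])
  }
})

test_that("cleanly separated classes can leave the unidentified band empty", {
  th <- fit_thresholds(data.frame(v = c(6, 7, 2, 3), w = c(5, 6, 1, 2)),
                       c(TRUE, TRUE, FALSE, FALSE))
  expect_gt(th$t_adl_xyz, th$t_fall_xyz)  # gap, not overlap
  expect_equal(triage(list(v = 4.5, w = 2.5), th), "Fall")
})
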