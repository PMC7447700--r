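# Nonlinear least-squares fitters and the SPAD calibration.

test_that("noise-free light-response curves round-trip through the fitter", {
  fit <- fit_light_response(gen_light_curve(truth_light()))
  expect_true(fit$converged)
  truth <- unlist(truth_light())
  expect_equal(coef(fit), truth[names(coef(fit))], tolerance = 1e-4)
  expect_lt(fit$sse, 1e-10)
  # deterministic: refitting the identical curve is bit-identical
  fit2 <- fit_light_response(gen_light_curve(truth_light()))
  expect_identical(coef(fit), coef(fit2))
})

test_that("light-response fitter guards degenerate and malformed input", {
  flat <- gas_exchange_curve(ppfd_ladder(), rep(5, 14), kind = "PPFD")
  fit <- fit_light_response(flat)
  expect_false(fit$converged)
  expect_match(fit$flags, "unidentifiable", all = FALSE)
  expect_error(fit_light_response(gas_exchange_curve(c(0, 100, 500, 900),
                                                     c(-2, 5, 15, 20),
                                                     kind = "PPFD")),
               "at least 5")
  expect_warning(fit_light_response(
    gas_exchange_curve(c(200, 300, 400, 500, 600),
                       nrh_pn(c(200, 300, 400, 500, 600), truth_light()),
                       kind = "PPFD")), "span")
})

test_that("noise-free A/Ci curves round-trip, with and without fixed Rd", {
  fit <- fit_aci(gen_aci_curve(truth_fvcb()))
  expect_true(fit$converged)
  expect_equal(coef(fit)[["vcmax"]], 105.91, tolerance = 1e-3)
  expect_equal(coef(fit)[["jmax"]], 191.66, tolerance = 1e-3)
  expect_equal(coef(fit)[["rd"]], 1.5, tolerance = 1e-2)

  fitf <- fit_aci(gen_aci_curve(truth_fvcb()), rd = 1.5)
  expect_equal(coef(fitf)[["vcmax"]], 105.91, tolerance = 1e-6)
  expect_equal(coef(fitf)[["jmax"]], 191.66, tolerance = 1e-6)
  expect_identical(fitf$rd_mode, "fixed")
  expect_named(coef(fitf), c("vcmax", "jmax"))
})

test_that("A/Ci fit flags jmax unidentifiable when all points are Rubisco-limited", {
  low_ladder <- c(150, 120, 100, 80, 50, 25)
  curve <- gen_aci_curve(truth_fvcb(), ladder = low_ladder)
  expect_warning(fit <- fit_aci(curve, rd = 1.5), "poorly covered")
  expect_true(all(fit$limitation == "Wc"))
  expect_match(fit$flags, "jmax unidentifiable", all = FALSE)
})

test_that("limitation labels split exactly at the fitted crossover Ci", {
  fit <- fit_aci(gen_aci_curve(truth_fvcb()), rd = 1.5)
  cistar <- fit$crossover_ci
  expect_equal(cistar, 421.6, tolerance = 1e-3)
  expect_true(all(fit$limitation[fit$data$driver < cistar] == "Wc"))
  expect_true(all(fit$limitation[fit$data$driver > cistar] == "Wj"))
})

test_that("A/Ci optimum matches an exhaustive grid search and dominates the truth SSE", {
  curve <- gen_aci_curve(truth_fvcb(), sigma = 0.5, seed = 42)
  fit <- fit_aci(curve, rd = 1.5)
  # brute-force 2-D grid at 0.5 resolution around the plausible region
  grid <- expand.grid(vcmax = seq(90, 120, by = 0.5),
                      jmax = seq(170, 210, by = 0.5))
  sse <- vapply(seq_len(nrow(grid)), function(r) {
    p <- fvcb_params(grid$vcmax[r], grid$jmax[r], 1.5)
    sum((curve$pn - fvcb_pn(curve$driver, p))^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  expect_lt(abs(coef(fit)[["vcmax"]] - best$vcmax), 0.5)
  expect_lt(abs(coef(fit)[["jmax"]] - best$jmax), 0.5)
  # optimizer dominance on noisy replicates
  for (s in 1:10) {
    cv <- gen_aci_curve(truth_fvcb(), sigma = 0.5, seed = s)
    f <- fit_aci(cv, rd = 1.5)
    sse_truth <- sum((cv$pn - fvcb_pn(cv$driver, truth_fvcb()))^2)
    expect_lte(f$sse, sse_truth + 1e-10)
  }
})

test_that("noise-free Richards trajectories round-trip through the fitter", {
  fit <- fit_richards(gen_grain_filling(truth_richards(), t_max = 40))
  expect_true(fit$converged)
  truth <- unlist(truth_richards())
  expect_equal(coef(fit), truth[names(coef(fit))], tolerance = 1e-3)
})

test_that("Richards fitter flags non-growing input instead of crashing", {
  tt <- seq(0, 40, by = 5)
  fit <- suppressWarnings(fit_richards(tt, seq(30, 14, length.out = 9)))
  expect_true(!fit$converged || length(fit$flags) > 0)
  expect_error(fit_richards(c(0, 5, 10), c(1, 2, 3)), "at least 6")
  expect_error(fit_richards(tt, rep(-1, 9)), "positive")
})

test_that("all three fitters recover random truths exactly at zero noise", {
  set.seed(31)
  for (k in 1:15) {
    pl <- rand_light_params()
    fl <- fit_light_response(gen_light_curve(pl))
    expect_equal(coef(fl), unlist(pl)[names(coef(fl))], tolerance = 1e-3)

    pa <- rand_fvcb_params()
    fa <- fit_aci(gen_aci_curve(pa), rd = pa$rd)
    expect_equal(coef(fa)[["vcmax"]], pa$vcmax, tolerance = 1e-3)
    expect_equal(coef(fa)[["jmax"]], pa$jmax, tolerance = 1e-3)

    pr <- rand_richards_params()
    fr <- fit_richards(gen_grain_filling(pr, t_max = 50))
    expect_equal(coef(fr), unlist(pr)[names(coef(fr))], tolerance = 1e-3)
  }
})

test_that("optimizer dominance holds for noisy light-response replicates", {
  for (s in 1:10) {
    cv <- gen_light_curve(truth_light(), sigma = 0.5, seed = s)
    f <- fit_light_response(cv)
    sse_truth <- sum((cv$pn - nrh_pn(cv$driver, truth_light()))^2)
    expect_lte(f$sse, sse_truth + 1e-10)
  }
})

test_that("fit objects expose the standard modelling interface", {
  fit <- fit_light_response(gen_light_curve(truth_light(), sigma = 0.3,
                                            seed = 5))
  expect_s3_class(fit, "photo_fit")
  expect_length(residuals(fit), 14)
  expect_equal(fitted(fit) + residuals(fit), fit$data$pn)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, 0), coef(fit)[["rd"]] * -1, ignore_attr = TRUE)
  expect_true(all(is.finite(fit$se)))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.photo_fit")
  expect_output(print(sm), "non-rectangular")
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_identical(simulate(fit, nsim = 3, seed = 9), sims)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("SPAD calibration recovers an exact line and maps SPAD 40 to 1.90", {
  spad <- c(20, 30, 40, 50, 60)
  cal <- fit_spad_calibration(spad, 0.30 + 0.04 * spad)
  expect_equal(cal$intercept, 0.30, tolerance = 1e-12)
  expect_equal(cal$slope, 0.04, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_equal(predict(cal, 40), 1.90)
  cal3 <- fit_spad_calibration(c(0, 1, 2), c(1, 2, 3))
  expect_equal(c(cal3$intercept, cal3$slope, cal3$r_squared), c(1, 1, 1))
})

test_that("SPAD calibration flags outliers, rejects constant readings, clamps negatives", {
  spad <- c(10, 20, 30, 40)
  chl <- 0.30 + 0.04 * spad
  chl[3] <- chl[3] + 0.5   # planted outlier
  cal <- fit_spad_calibration(spad, chl)
  expect_lt(cal$r_squared, 1)
  expect_equal(which.max(abs(cal$residuals)), 3L)
  expect_output(summary(cal), "max")
  expect_error(fit_spad_calibration(c(30, 30, 30), c(1, 2, 3)), "constant")
  expect_error(fit_spad_calibration(c(30, 40), c(1, 2)), "at least 3")
  neg <- fit_spad_calibration(c(20, 30, 40), c(0.1, 0.5, 0.9))
  expect_warning(out <- predict(neg, 0), "clamped")
  expect_equal(out, 0)
})
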