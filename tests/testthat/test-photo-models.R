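# Forward photosynthesis and growth models.

test_that("light response collapses to -Rd at zero PPFD and rejects bad input", {
  set.seed(11)
  for (k in 1:20) {
    p <- rand_light_params()
    expect_equal(nrh_pn(0, p), -p$rd)
  }
  expect_error(nrh_pn(-1, truth_light()), "non-negative")
  expect_error(light_params(pn_max = -1, aqy = 0.09), "pn_max")
  expect_error(light_params(46, 0.09, theta = 1.2), "theta")
})

test_that("theta = 1 reduces the hyperbola to the Blackman limit min(aI, Pnmax) - Rd", {
  # at theta = 1 the discriminant is (aI - Pnmax)^2, so the root collapses
  p <- light_params(pn_max = 46.03, aqy = 0.09, theta = 1, rd = 2)
  expect_equal(nrh_pn(200, p), min(0.09 * 200, 46.03) - 2)  # = 16.0
  igrid <- seq(0, 2500, by = 50)
  expect_equal(nrh_pn(igrid, p), pmin(0.09 * igrid, 46.03) - 2,
               tolerance = 1e-10)
})

test_that("theta -> 0 limit agrees with the rectangular-hyperbola closed form", {
  closed <- function(i, a, pm) a * i * pm / (a * i + pm)
  near0 <- light_params(46.03, 0.09, theta = 1e-9, rd = 0)
  at0 <- light_params(46.03, 0.09, theta = 0, rd = 0)
  expect_equal(nrh_pn(500, at0), closed(500, 0.09, 46.03), tolerance = 1e-12)
  expect_lt(abs(nrh_pn(500, near0) - nrh_pn(500, at0)), 1e-4)
})

test_that("light response is nondecreasing in PPFD with supremum pn_max - rd", {
  set.seed(12)
  igrid <- seq(0, 5000, by = 25)
  for (k in 1:20) {
    p <- rand_light_params()
    v <- nrh_pn(igrid, p)
    expect_true(all(diff(v) >= -1e-10))
    expect_lt(max(v), p$pn_max - p$rd + 1e-8)
    expect_equal(nrh_pn(1e9, p), p$pn_max - p$rd, tolerance = 1e-4)
  }
})

test_that("carboxylation-limited rate matches hand evaluation and saturates at vcmax", {
  p <- truth_fvcb()
  expect_equal(fvcb_wc(0, p), 0)
  # 105.91 * 380 / (380 + 404 * (1 + 210/278))
  expect_equal(fvcb_wc(380, p), 105.91 * 380 / (380 + 404 * (1 + 210 / 278)),
               tolerance = 1e-12)
  expect_equal(fvcb_wc(380, p), 36.95, tolerance = 1e-3)
  ci <- c(10, 100, 1000, 1e4, 1e6)
  w <- fvcb_wc(ci, p)
  expect_true(all(diff(w) > 0))
  expect_true(all(w < p$vcmax))
  expect_equal(fvcb_wc(1e9, p), p$vcmax, tolerance = 1e-5)
  expect_error(fvcb_wc(-5, p), "non-negative")
})

test_that("RuBP-regeneration-limited rate matches hand evaluation and saturates at jmax/4", {
  p <- truth_fvcb()
  expect_equal(fvcb_wj(0, p), 0)
  expect_equal(fvcb_wj(380, p), 191.66 * 380 / (4 * 380 + 8 * 45),
               tolerance = 1e-12)
  expect_equal(fvcb_wj(380, p), 38.74, tolerance = 1e-3)
  expect_equal(fvcb_wj(1e9, p), p$jmax / 4, tolerance = 1e-5)
  w <- fvcb_wj(c(10, 100, 1000, 1e5), p)
  expect_true(all(diff(w) > 0))
})

test_that("net A/Ci rate is the min rule and is continuous at the crossover", {
  p <- truth_fvcb()
  expect_equal(fvcb_pn(0, p), -p$rd)
  expect_equal(fvcb_pn(380, p), min(fvcb_wc(380, p), fvcb_wj(380, p)) - 1.5)
  # huge vcmax: Wj always the minimum
  ph <- fvcb_params(vcmax = 1e6, jmax = 191.66, rd = 1.5)
  ci <- co2_ladder()
  expect_equal(fvcb_pn(ci, ph), fvcb_wj(ci, ph) - 1.5)
  # continuity across the crossover
  cistar <- fvcb_crossover_ci(p)
  eps <- 1e-7
  expect_lt(abs(fvcb_pn(cistar + eps, p) - fvcb_pn(cistar - eps, p)), 1e-6)
})

test_that("crossover Ci matches the closed form, a bisection oracle, and degenerates to NA", {
  p <- truth_fvcb()
  cistar <- fvcb_crossover_ci(p)
  expect_equal(cistar, 421.6, tolerance = 1e-3)
  expect_lt(abs(fvcb_wc(cistar, p) - fvcb_wj(cistar, p)), 1e-9)
  # independent numeric root of Wc - Wj
  root <- uniroot(function(ci) fvcb_wc(ci, p) - fvcb_wj(ci, p),
                  c(50, 1800), tol = 1e-12)$root
  expect_equal(cistar, root, tolerance = 1e-9)
  expect_true(is.na(fvcb_crossover_ci(fvcb_params(50, 200))))  # jmax = 4 vcmax
  expect_true(is.na(fvcb_crossover_ci(fvcb_params(50, 300))))  # denominator < 0
})

test_that("canonical (Ci - Gamma*) numerators are available but never the default", {
  p <- truth_fvcb()
  k <- kinetic_constants()
  expect_equal(fvcb_wc(380, p, k, canonical = TRUE),
               105.91 * (380 - 45) / (380 + 404 * (1 + 210 / 278)),
               tolerance = 1e-12)
  expect_equal(fvcb_wj(380, p, k, canonical = TRUE),
               191.66 * (380 - 45) / (4 * 380 + 8 * 45), tolerance = 1e-12)
  # default call is the plain-Ci form
  expect_gt(fvcb_wc(380, p), fvcb_wc(380, p, k, canonical = TRUE))
})

test_that("Richards mass has the right asymptote, logistic special case and monotonicity", {
  p <- truth_richards()
  expect_equal(richards_mass(1e6, p), p$a, tolerance = 1e-9)
  # n = 1 logistic: a / (1 + b e^{-kt})
  plog <- richards_params(a = 27, b = 20, k = 0.2, n = 1)
  expect_equal(richards_mass(0, plog), 27 / 21, tolerance = 1e-12)
  tt <- seq(0, 80, by = 0.5)
  w <- richards_mass(tt, p)
  expect_true(all(diff(w) > 0))
  expect_true(all(w > 0 & w < p$a))
})

test_that("Richards rate is the derivative of mass and is unimodal, vanishing at infinity", {
  set.seed(13)
  for (k in 1:10) {
    p <- rand_richards_params()
    # finite-difference oracle at t = 10
    h <- 1e-5
    fd <- (richards_mass(10 + h, p) - richards_mass(10 - h, p)) / (2 * h)
    expect_equal(richards_rate(10, p), fd, tolerance = 1e-6)
    tt <- seq(0, 120, by = 0.5)
    r <- richards_rate(tt, p)
    expect_true(all(r >= 0))
    # single interior maximum: sign of the difference changes at most once
    s <- sign(diff(r))
    s <- s[s != 0]
    expect_lte(sum(diff(s) != 0), 1)
  }
  # fundamental theorem: integral of rate = mass increment
  p <- truth_richards()
  quad <- integrate(function(t) richards_rate(t, p), 0, 40,
                    rel.tol = 1e-10)$value
  expect_equal(quad, richards_mass(40, p) - richards_mass(0, p),
               tolerance = 1e-6)
  expect_lt(richards_rate(1e4, p), 1e-12)
})
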