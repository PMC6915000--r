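# The symmetry function, its parameterisation and classification.

test_that("curve_range is the scalar whole-cycle max minus min", {
  expect_equal(curve_range(mk_curve(rep(3, 101))), 0)
  v <- c(-10.4, seq(-10, 34, length.out = 99), 34.6)
  expect_equal(curve_range(mk_curve(v)), 45.0)
  A <- 7.3
  expect_equal(curve_range(A * sin(2 * pi * grid_pct / 100 + 0.4)),
               2 * A, tolerance = 1e-3)  # grid may just miss the analytic peak
})

test_that("a constant 1-degree side difference scales inversely with ROM", {
  base5 <- 2.5 + 2.5 * cos(2 * pi * grid_pct / 100)   # range 5 deg
  sf5 <- symmetry_function(mk_curve(base5), mk_curve(base5 - 1))
  expect_equal(sf5$values, rep(20, 101))

  base50 <- 25 * cos(2 * pi * grid_pct / 100)         # range 50 deg
  sf50 <- symmetry_function(mk_curve(base50), mk_curve(base50 - 1))
  expect_equal(sf50$values, rep(2, 101))

  expect_equal(symmetry_function(mk_curve(base50), mk_curve(base50))$values,
               rep(0, 101))
})

test_that("equal-range antiphase curves touch the +/-200% bound", {
  R <- 12
  up <- R / 2 + R / 2 * cos(2 * pi * grid_pct / 100)    # spans [0, R], max at 0%CT
  dn <- -R / 2 + R / 2 * cos(2 * pi * grid_pct / 100 + pi)  # spans [-R, 0], min at 0%CT
  sf <- symmetry_function(mk_curve(up), mk_curve(dn))
  expect_equal(max(sf$values), 200)
  sf_sw <- symmetry_function(mk_curve(dn), mk_curve(up))
  expect_equal(min(sf_sw$values), -200)
})

test_that("parameterization satisfies rom = peak_max - peak_min on SF peak pairs", {
  mk_sf_like <- function(lo, hi) c(lo, seq(lo + 1, hi - 1, length.out = 99), hi)
  cases <- list(hip = c(-64.6, 44.3, 108.9),
                knee = c(-17.4, 15.9, 33.3),
                ankle = c(-7.3, 31.4, 38.7))
  for (cs in cases) {
    p <- parameterize(mk_sf_like(cs[1], cs[2]))
    expect_equal(p$peak_min, cs[1])
    expect_equal(p$peak_max, cs[2])
    expect_equal(p$rom, p$peak_max - p$peak_min)
    expect_equal(p$rom, cs[3], tolerance = 1e-9)
  }
  # peaks printed to one decimal carry rounding: identity holds within 0.15
  p <- parameterize(mk_sf_like(-146.2, 9.3))
  expect_lt(abs(p$rom - 155.4), 0.15)
})

test_that("parameterization breaks ties at the first grid occurrence", {
  p <- parameterize(mk_curve(rep(4, 101)))
  expect_equal(p$rom, 0)
  expect_equal(p$t_min, 0)
  expect_equal(p$t_max, 0)
  v <- rep(0, 101)
  v[c(21, 61)] <- 5
  v[c(31, 71)] <- -5
  p <- parameterize(mk_curve(v))
  expect_equal(p$t_max, 20)
  expect_equal(p$t_min, 30)
})

test_that("classification follows the 10%/15% conventions", {
  mk_params <- function(s) parameterize(c(rep(0, 100), s))
  expect_equal(as.character(classify_asymmetry(mk_params(5))), "symmetric")
  expect_equal(as.character(classify_asymmetry(mk_params(9.99))), "symmetric")
  expect_equal(as.character(classify_asymmetry(mk_params(10))), "borderline")
  expect_equal(as.character(classify_asymmetry(mk_params(12))), "borderline")
  expect_equal(as.character(classify_asymmetry(mk_params(14.99))), "borderline")
  expect_equal(as.character(classify_asymmetry(mk_params(15))), "asymmetric")
  expect_equal(as.character(classify_asymmetry(mk_params(-20))), "asymmetric")
  # mean_abs needs the curve, and averages |SF|
  sfc <- structure(list(values = c(rep(-12, 50), rep(12, 51)),
                        pct_ct = grid_pct), class = "sf_curve")
  expect_equal(as.character(classify_asymmetry(sfc, "mean_abs")), "borderline")
  expect_error(classify_asymmetry(mk_params(5), "mean_abs"),
               class = "gaitsf_input_error")
})

test_that("SF peaks are localised to their gait phase", {
  bump <- function(at, sign) {
    v <- numeric(101)
    v[at + 1] <- sign * 30
    v
  }
  base <- 5 * cos(2 * pi * grid_pct / 100)
  for (cs in list(list(t = 8, phase = "LR"), list(t = 54, phase = "TDSt"),
                  list(t = 95, phase = "TSw"))) {
    fit <- gait_sf(mk_curve(base + bump(cs$t, -1)), mk_curve(base))
    expect_equal(fit$params$t_min, cs$t)
    expect_equal(fit$peak_phases$phase[fit$peak_phases$peak == "min"],
                 cs$phase)
  }
})

test_that("near-constant curve pairs are rejected, not amplified", {
  flat <- mk_curve(rep(1, 101))
  expect_error(symmetry_function(flat, mk_curve(rep(2, 101))),
               class = "gaitsf_degenerate_range")
  expect_error(gait_sf(flat, flat), class = "gaitsf_degenerate_range")
  # mismatched inputs fail validation, not arithmetic
  expect_error(symmetry_function(mk_curve(rnorm(101)),
                                 mk_curve(rnorm(101), joint = "knee_flexext")),
               class = "gaitsf_input_error")
})

test_that("SF obeys its algebraic invariants on random curves", {
  set.seed(42)
  for (i in 1:50) {
    v1 <- rand_curve_values()
    v2 <- rand_curve_values()
    a <- mk_curve(v1)
    b <- mk_curve(v2)
    sf_ab <- symmetry_function(a, b)$values
    # antisymmetry
    expect_equal(sf_ab, -symmetry_function(b, a)$values, tolerance = 1e-12)
    # common shift invariance
    cshift <- rnorm(1, 0, 20)
    expect_equal(symmetry_function(mk_curve(v1 + cshift),
                                   mk_curve(v2 + cshift))$values,
                 sf_ab, tolerance = 1e-9)
    # common positive scale invariance
    k <- runif(1, 0.2, 5)
    expect_equal(symmetry_function(mk_curve(k * v1), mk_curve(k * v2))$values,
                 sf_ab, tolerance = 1e-9)
    # one-sided offset law: closed-form constant change
    delta <- rnorm(1, 0, 5)
    denom <- 0.5 * (curve_range(v1) + curve_range(v2))
    expect_equal(symmetry_function(mk_curve(v1 + delta), b)$values,
                 sf_ab + 100 * delta / denom, tolerance = 1e-9)
    # brute-force oracle
    expect_equal(sf_ab, sf_oracle(v1, v2), tolerance = 1e-12)
  }
})

test_that("gait_sf assembles a coherent classed result", {
  first <- mk_curve(12 + 22 * cos(2 * pi * grid_pct / 100), side = "right")
  second <- mk_curve(12 + 15 * cos(2 * pi * grid_pct / 100), side = "left")
  fit <- gait_sf(first, second)
  expect_s3_class(fit, "gait_sf")
  expect_equal(fit$params$rom, fit$params$peak_max - fit$params$peak_min,
               tolerance = 1e-9)
  expect_equal(fit$curve$first_label, "right")
  expect_named(coef(fit), c("peak_min", "t_min", "peak_max", "t_max", "rom"))
  expect_output(print(fit), "Symmetry function")
  expect_output(print(summary(fit)), "dominance")
  expect_s3_class(fit$peak_phases, "data.frame")
})
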