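# Synthetic bilateral gait: templates, asymmetry mechanisms, presets.

side_curve <- function(set, side) {
  nset <- normalize_set(set)
  sides <- vapply(nset, function(c) c$side, "")
  nset[[which(sides == side)[1]]]
}

test_that("templates render deterministically with the requested shape", {
  tpl <- template_spec("hip_flexext",
                       data.frame(harmonic = 1, amplitude = 5, phase = 0),
                       baseline = 10)
  cv <- render_template(tpl)
  expect_equal(curve_range(cv), 10)
  # the analytic mean is the baseline (grid mean over one full period,
  # duplicated endpoint excluded)
  expect_equal(mean(cv$values[1:100]), 10, tolerance = 1e-12)

  flat <- template_spec("hip_flexext",
                        data.frame(harmonic = 1, amplitude = 0, phase = 0),
                        baseline = 4)
  expect_equal(render_template(flat)$values, rep(4, 101))
  expect_error(template_spec("hip_flexext", data.frame()),
               class = "gaitsf_input_error")
})

test_that("default templates land in the healthy ROM bands", {
  bands <- list(hip_flexext = 44.3, knee_flexext = 57.3,
                ankle_dorsiplantar = 32.0)
  for (j in names(bands)) {
    rom <- curve_range(render_template(default_template(j)))
    expect_gt(rom, 0.8 * bands[[j]])
    expect_lt(rom, 1.2 * bands[[j]])
  }
  expect_lt(curve_range(render_template(default_template("pelvis_tilt"))), 5)
  expect_equal(curve_range(render_template(
    default_template("pelvis_tilt", pelvis_rom = "table"))), 1.0,
    tolerance = 1e-9)
})

test_that("an identity transform with zero noise gives SF identically zero", {
  tpl <- default_template("hip_flexext")
  set <- simulate_subject(tpl, asymmetry_spec(1, 0, 0, 0), n_cycles = 1,
                          seed = 3, sampling = "grid")
  sf <- symmetry_function(side_curve(set, "right"), side_curve(set, "left"))
  expect_equal(sf$values, rep(0, 101))
})

test_that("a 1-degree offset against a 50-degree range reads as 2% SF", {
  tpl <- template_spec("knee_flexext",
                       data.frame(harmonic = 1, amplitude = 25, phase = 0),
                       baseline = 30)
  set <- simulate_subject(tpl, asymmetry_spec(1, 0, offset = 1, noise_sd = 0),
                          n_cycles = 1, seed = 3, sampling = "grid")
  # affected (left) carries the +1 deg offset: left-minus-right SF is +2%
  sf <- symmetry_function(side_curve(set, "left"), side_curve(set, "right"))
  expect_equal(sf$values, rep(2, 101), tolerance = 1e-12)
})

test_that("amplitude scaling matches its closed form pointwise", {
  a <- 0.7
  tpl <- default_template("hip_flexext")
  set <- simulate_subject(tpl, asymmetry_spec(a, 0, 0, 0), n_cycles = 1,
                          seed = 3, sampling = "grid")
  sf <- symmetry_function(side_curve(set, "left"), side_curve(set, "right"))
  x <- render_template(tpl)$values
  r <- curve_range(x)
  oracle <- 100 * (a - 1) * (x - tpl$baseline) / (0.5 * (a + 1) * r)
  expect_equal(sf$values, oracle, tolerance = 1e-12)
})

test_that("simulation is reproducible under a fixed seed", {
  tpl <- default_template("knee_flexext")
  s1 <- simulate_subject(tpl, asymmetry_spec(0.8, 5, 1, 0.3), 3, seed = 77)
  s2 <- simulate_subject(tpl, asymmetry_spec(0.8, 5, 1, 0.3), 3, seed = 77)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  c1 <- preset_cohort("uTHR", 2, seed = 123, n_cycles = 2)
  c2 <- preset_cohort("uTHR", 2, seed = 123, n_cycles = 2)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- preset_cohort("uTHR", 2, seed = 124, n_cycles = 2)
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("asymmetry specs validate their domain", {
  expect_error(asymmetry_spec(0), class = "gaitsf_input_error")
  expect_error(asymmetry_spec(1, 50), class = "gaitsf_input_error")
  expect_error(asymmetry_spec(1, 0, 0, -1), class = "gaitsf_input_error")
  expect_error(simulate_subject(default_template("hip_flexext"),
                                asymmetry_spec(), n_cycles = 1),
               class = "gaitsf_input_error")  # seed is mandatory
})

test_that("uTHR preset reduces involved hip excursion", {
  coh <- preset_cohort("uTHR", 3, seed = 9, n_cycles = 2)
  tab <- group_param_table(coh)
  rom <- function(side) tab$mean[tab$joint == "hip_flexext" &
                                 tab$side == side & tab$parameter == "rom"]
  expect_lt(rom("involved"), rom("uninvolved"))
})

test_that("SF range inflates with measurement noise", {
  tpl <- default_template("hip_flexext")
  mean_rom <- vapply(c(0, 0.5, 2), function(ns) {
    mean(vapply(1:5, function(s) {
      set <- simulate_subject(tpl, asymmetry_spec(1, 0, 1, ns), 1, seed = s)
      sf <- symmetry_function(side_curve(set, "left"), side_curve(set, "right"))
      parameterize(sf)$rom
    }, 0))
  }, 0)
  expect_true(all(diff(mean_rom) > 0))
})
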