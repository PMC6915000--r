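# Angle-curve parameterisation and the group summary table.

test_that("angle_params extracts peaks, timings and ROM", {
  cosine <- mk_curve(10 + 5 * cos(2 * pi * grid_pct / 100))
  p <- angle_params(cosine)
  expect_equal(p$peak_max, 15)
  expect_equal(p$peak_min, 5)
  expect_equal(p$rom, 10)
  expect_equal(p$t_max, 0)
  expect_equal(p$t_min, 50)

  mono <- mk_curve(seq(-3, 40, length.out = 101))
  p <- angle_params(mono)
  expect_equal(p$t_min, 0)
  expect_equal(p$t_max, 100)
  expect_error(angle_params(1:101), class = "gaitsf_input_error")
})

mk_subject_cycles <- function(subject_id, amps, joint = "hip_flexext",
                              side = "right", group = "normal",
                              phase = 0) {
  lapply(seq_along(amps), function(i)
    angle_cycle(0:100,
                10 + amps[i] * cos(2 * pi * grid_pct / 100 + phase),
                subject_id, group, side, joint, i))
}

test_that("identical subjects collapse to SD zero", {
  cycles <- unlist(lapply(c("A", "B", "C"), mk_subject_cycles,
                          amps = c(5, 5)), recursive = FALSE)
  tab <- group_param_table(subject_set(cycles))
  expect_true(all(tab$sd == 0))
  expect_true(all(tab$n_subjects == 3))
  expect_equal(tab$mean[tab$parameter == "rom"], 10)
})

test_that("known per-subject ROMs give the hand-computed mean and sample SD", {
  # amplitudes 20, 22.5, 25 -> per-subject ROMs 40, 45, 50
  cycles <- c(mk_subject_cycles("A", 20), mk_subject_cycles("B", 22.5),
              mk_subject_cycles("C", 25))
  tab <- group_param_table(subject_set(cycles))
  rom <- tab[tab$parameter == "rom", ]
  expect_equal(rom$mean, 45)
  expect_equal(rom$sd, 5)   # sd({40,45,50}) by the unbiased formula
})

test_that("parameters are extracted per cycle, then averaged", {
  # two antiphase cycles: the mean curve is flat (ROM 0), but per-cycle
  # ROMs are both 10 — the table must report 10, proving cycle-level
  # extraction precedes averaging.
  cyc1 <- mk_subject_cycles("A", 5)[[1]]
  cyc2 <- mk_subject_cycles("A", 5, phase = pi)[[1]]
  cyc2$cycle_index <- 2L
  tab <- group_param_table(subject_set(list(cyc1, cyc2)))
  expect_equal(tab$mean[tab$parameter == "rom"], 10)
})

test_that("a single-subject cohort reproduces that subject with flagged SD", {
  tab <- group_param_table(subject_set(mk_subject_cycles("solo", 7)))
  expect_equal(tab$mean[tab$parameter == "rom"], 14)
  expect_true(all(is.na(tab$sd)))
  expect_true(all(tab$single_subject))
})

test_that("simulated uTHR hip ROM is reduced relative to normal", {
  uthr <- preset_cohort("uTHR", n_subjects = 3, seed = 5, n_cycles = 2)
  norm <- preset_cohort("normal", n_subjects = 3, seed = 6, n_cycles = 2)
  tu <- group_param_table(uthr)
  tn <- group_param_table(norm)
  hip_rom <- function(t, side) t$mean[t$parameter == "rom" &
                                      t$joint == "hip_flexext" &
                                      t$side == side]
  expect_lt(hip_rom(tu, "involved"), hip_rom(tu, "uninvolved"))
  expect_lt(hip_rom(tu, "involved"), hip_rom(tn, "right"))
  expect_lt(hip_rom(tu, "uninvolved"), hip_rom(tn, "right"))
})

test_that("wide export has one column per group-side cell", {
  cycles <- c(mk_subject_cycles("A", 5, side = "right"),
              mk_subject_cycles("A", 4, side = "left"))
  wide <- param_table_wide(group_param_table(subject_set(cycles)))
  expect_true(all(c("normal.left", "normal.right") %in% names(wide)))
  expect_equal(nrow(wide), 5)  # one joint x five parameters
})
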