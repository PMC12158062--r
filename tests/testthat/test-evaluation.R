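# Evaluation pipeline: baseline series, MAE arithmetic against by-hand
# oracles, the three-estimator report, splits and the ablation shape.

test_that("keytel series: constancy, frozen value, clamping, filling", {
  prof <- fix_profile_male()
  proto <- fix_protocol(dur = 20L)
  s <- generate_session(prof, proto, noise_sd = 0, tau_s = 0, seed = 1)
  s$data$hr_bpm[] <- 120
  ky <- keytel_series(s)
  expect_true(all(ky == ky[1]))
  # oracle: (-55.0969 + 0.6309*120 + 0.1988*70 + 0.2017*30) / 4.184 / 60
  expect_close(ky[1], 40.5781 / 4.184 / 60, tol = 1e-12)
  # below the male zero crossing the clamped series is 0
  s$data$hr_bpm[] <- 40
  expect_true(all(keytel_series(s) == 0))
  expect_gt(attr(keytel_series(s), "n_clamped"), 0)
  expect_lt(keytel_series(s, clamp = FALSE)[1], 0)
  # missing heart-rate seconds are forward-filled, leading gap back-filled
  s$data$hr_bpm[] <- 120
  s$data$hr_bpm[c(1, 2, 7)] <- NA
  s$data$hr_bpm[6] <- 100
  ky <- keytel_series(s)
  expect_identical(attr(ky, "n_filled"), 3L)
  # t = 7 carried forward from the last known second (HR 100 at t = 6)
  expect_close(ky[7], convert_energy(ee_keytel(prof, 100), "kJ/min",
                                     "kcal/s"), tol = 1e-12)
  expect_close(ky[1], ky[4], tol = 1e-12)    # backfilled from first known
  expect_true(anyNA(keytel_series(s, fill = "none")))
  # the baseline is independent of ground truth: changing VO2 changes
  # nothing
  s2 <- s
  s2$data$vo2_ml_kg_min <- s2$data$vo2_ml_kg_min * 2
  expect_identical(as.numeric(keytel_series(s2)), as.numeric(ky))
})

test_that("met series: frozen sitting value, piecewise constant,
           linear in weight", {
  s70 <- fix_session(dur = 30L, noise_sd = 0)
  m <- met_series(s70)
  sit <- s70$data$activity == "Sitting"
  expect_close(m[sit], rep(1 * 70 * 3.5 / 200 / 60, sum(sit)), tol = 1e-12)
  expect_identical(length(unique(m)), 6L)
  s140 <- generate_session(participant_profile(140, 175, 30, 1),
                           fix_protocol(30L), noise_sd = 0, seed = 11)
  expect_close(met_series(s140), 2 * m, tol = 1e-12)
  # supplied segment table and offset
  tbl <- c(Sitting = 1, Standing = 1.2, Cycle1 = 10, Cycle2 = 14,
           Run1 = 8, Run2 = 12)
  expect_close(met_series(s70, met_per_segment = tbl), m, tol = 1e-12)
  expect_close(met_series(s70, met_offset = 2) - m,
               rep(2 * 70 * 3.5 / 200 / 60, length(m)), tol = 1e-12)
  expect_error(met_series(s70, met_per_segment = tbl[-1]), "misses")
  s_na <- s70
  s_na$data$met_true[3] <- NA
  expect_error(met_series(s_na), "met_true")
})

test_that("mae and segment_mae against a by-hand 6-point oracle", {
  pred <- c(0.02, 0.03, 0.10, 0.12, 0.20, 0.18)
  gt <- c(0.02, 0.05, 0.08, 0.12, 0.25, 0.10)
  # |diff| = 0.00 0.02 0.02 0.00 0.05 0.08 -> mean 0.17/6
  expect_close(mae(pred, gt), 0.17 / 6, tol = 1e-12)
  labels <- c("Sitting", "Sitting", "Cycle1", "Cycle1", "Run1", "Run1")
  sm <- segment_mae(pred, gt, labels)
  expect_close(sm[["Sitting"]], 0.01, tol = 1e-12)
  expect_close(sm[["Cycle1"]], 0.01, tol = 1e-12)
  expect_close(sm[["Run1"]], 0.065, tol = 1e-12)
  expect_error(mae(pred, gt[-1]), "length")
  # invariances: relabeling permutes, constant offset is uniform,
  # time-shifting both series together changes nothing
  expect_identical(mae(pred, gt), mae(rev(pred), rev(gt)))
  sm2 <- segment_mae(pred + 0.01, pred, labels)
  expect_close(unname(sm2), rep(0.01, 3), tol = 1e-12)
  expect_identical(mae(pred, pred), 0)
})

test_that("three-estimator report: shape, Total invariant, oracle agent
           patterns on noise-free data", {
  sessions <- list(
    generate_session(fix_profile_male(), fix_protocol(40L), noise_sd = 0,
                     seed = 21),
    generate_session(fix_profile_female(), fix_protocol(40L), noise_sd = 0,
                     seed = 22)
  )
  rep0 <- compare_methods(oracle_agent(), sessions)
  expect_s3_class(rep0, "ee_eval_report")
  expect_identical(rep0$table$method, c("ours", "keytel", "met"))
  expect_identical(ncol(rep0$table), 8L)   # method + Total + 6 segments
  # Total equals the duration-weighted mean of the segment MAEs
  durations <- table(do.call(rbind, rep0$traces)$activity)
  for (i in 1:3) {
    segs <- as.numeric(rep0$table[i, levels(droplevels(
      rep0$traces[[1]]$activity))])
    expect_close(rep0$table$Total[i],
                 sum(segs * as.numeric(durations)) / sum(durations),
                 tol = 1e-9)
  }
  # with true MET labels and a noise-free lag-free world, the MET baseline
  # is near-exact at rest
  s_nolag <- generate_session(fix_profile_male(), fix_protocol(40L),
                              noise_sd = 0, tau_s = 0, seed = 23)
  repn <- compare_methods(oracle_agent(), s_nolag)
  expect_lt(repn$table$Sitting[repn$table$method == "met"], 1e-12)
  # mis-specifying MET by +2 breaks the MET baseline on every activity
  # segment while the grid-limited oracle stays at the quantization floor
  rep2 <- compare_methods(oracle_agent(), sessions, met_offset = 2)
  for (sg in c("Cycle1", "Cycle2", "Run1", "Run2")) {
    expect_lt(rep2$table[[sg]][1], rep2$table[[sg]][3])
  }
  expect_identical(rep2$notes$met_offset, 2)
})

test_that("report serialization round-trips", {
  dir <- withr::local_tempdir()
  s <- fix_session(dur = 30L, noise_sd = 1, seed = 31)
  rep0 <- compare_methods(oracle_agent(), s)
  write_report(rep0, dir)
  expect_true(all(file.exists(file.path(dir, c("report.csv", "report.json",
                                               "traces.csv")))))
  back <- read_report(dir)
  expect_equal(back$table, rep0$table, tolerance = 1e-12)
  expect_identical(back$notes$n_sessions, rep0$notes$n_sessions)
})

test_that("leave-participants-out split holds out one male + one female", {
  sessions <- list(
    fix_session(fix_profile_male(), dur = 20L, seed = 1),
    fix_session(participant_profile(80, 180, 35, 1, id = "M2"), dur = 20L,
                seed = 2),
    fix_session(fix_profile_female(), dur = 20L, seed = 3),
    fix_session(participant_profile(55, 160, 28, 0, id = "F2"), dur = 20L,
                seed = 4)
  )
  sp <- split_sessions(sessions)
  expect_length(sp$test, 2L)
  g <- vapply(sp$test, function(s) s$profile$gender_flag, integer(1))
  expect_setequal(g, c(0L, 1L))
  expect_identical(sum(sp$manifest$role == "test"), 2L)
  # single-gender fallback
  expect_warning(sp1 <- split_sessions(sessions[c(1, 2, 2)]), "gender")
  expect_length(sp1$test, 2L)
})

test_that("scenario-length ablation reports one row per length", {
  sessions <- lapply(1:4, function(i) {
    generate_session(
      participant_profile(60 + 5 * i, 165 + 3 * i, 25 + i, i %% 2,
                          id = paste0("P", i)),
      fix_protocol(30L), noise_sd = 0, seed = 40 + i)
  })
  cfg <- dqn_config(epochs = 1L, warmup = 50L, train_stride_s = 60L,
                    seed = 13L)
  ab <- scenario_length_ablation(sessions, cfg, lengths = c(120L, 60L))
  expect_identical(ab$scenario, c("2Min", "1Min"))
  expect_identical(ab$window_length_s, c(120L, 60L))
  expect_true(all(is.finite(ab$mae)))
  # seeded: identical on re-run
  expect_identical(scenario_length_ablation(sessions, cfg,
                                            lengths = c(120L, 60L)), ab)
})
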