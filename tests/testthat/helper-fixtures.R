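# Shared fixtures: small deterministic profiles, protocols and sessions.
# Everything is generated in code; nothing is read from disk.

fix_profile_male <- function() participant_profile(70, 175, 30, 1, id = "M1")
fix_profile_female <- function() participant_profile(60, 165, 25, 0, id = "F1")

# short protocol (6 segments x `dur` s) with fixed MET levels, so sessions
# used in unit tests stay small and fully determined
fix_protocol <- function(dur = 100L,
                         mets = c(Sitting = 1, Standing = 1.2, Cycle1 = 10,
                                  Cycle2 = 14, Run1 = 8, Run2 = 12)) {
  default_protocol(met_levels = mets, segment_duration_s = dur)
}

fix_session <- function(profile = fix_profile_male(), dur = 100L,
                        noise_sd = 0, tau_s = 30, seed = 11L, ...) {
  generate_session(profile, fix_protocol(dur), noise_sd = noise_sd,
                   tau_s = tau_s, seed = seed, ...)
}

# an agent without training (seeded init), for API-level tests
fix_untrained_agent <- function(session, seed = 5L) {
  train_dqn(list(session), dqn_config(epochs = 0L, seed = seed,
                                      window_length_s = 60L,
                                      train_stride_s = 60L))
}

expect_close <- function(object, expected, tol = 1e-9) {
  testthat::expect_true(
    all(abs(object - expected) <= tol * pmax(1, abs(expected))),
    label = sprintf("max rel err %.3g", max(abs(object - expected) /
                                              pmax(1, abs(expected))))
  )
}
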