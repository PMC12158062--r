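# DQN agent: network contracts, exploration, replay FIFO, TD-update
# fixed points, training determinism, and prediction bounds.

test_that("q_values: 201 outputs, deterministic, seeded init reproducible", {
  s <- fix_session(dur = 30L)
  agent <- fix_untrained_agent(s)
  st <- c(70, 175, 30, 1, 120)
  q <- q_values(agent, st)
  expect_length(q, 201L)
  expect_true(all(is.finite(q)))
  expect_identical(q, q_values(agent, st))
  agent2 <- fix_untrained_agent(s)
  expect_identical(agent$net, agent2$net)
  expect_identical(qnet_init(seed = 1), qnet_init(seed = 1))
  expect_false(identical(qnet_init(seed = 1), qnet_init(seed = 2)))
  expect_error(qnet_forward(agent$net, c(1, 2, 3)), "dimension")
})

test_that("select_action: greedy limit, uniform exploration, seeded", {
  s <- fix_session(dur = 30L)
  agent <- fix_untrained_agent(s)
  st <- c(70, 175, 30, 1, 120)
  greedy <- which.max(q_values(agent, st)) - 1L
  expect_true(all(replicate(20, select_action(agent, st, 0)) == greedy))
  # epsilon = 1: empirical distribution uniform over 201 actions
  set.seed(99)
  acts <- replicate(1e5, select_action(agent, st, 1))
  expect_identical(sort(unique(acts)), 0:200)
  p <- stats::chisq.test(table(factor(acts, levels = 0:200)))$p.value
  expect_gt(p, 1e-4)
  # seeded rng reproduces the sequence
  a1 <- withr::with_seed(7, replicate(50, select_action(agent, st, 0.5)))
  a2 <- withr::with_seed(7, replicate(50, select_action(agent, st, 0.5)))
  expect_identical(a1, a2)
})

test_that("replay buffer: FIFO eviction and capacity under heavy pushing", {
  cap <- 500L
  buf <- replay_buffer(cap, state_dim = 2L)
  n_push <- 1e6L
  # pushes carry their index so eviction order is checkable
  for (i in seq_len(n_push)) {
    replay_push(buf, c(i, i), i %% 201L, 0, c(i, i), FALSE)
  }
  expect_identical(replay_size(buf), cap)
  # survivors are exactly the newest `cap` entries (oldest-first eviction)
  expect_setequal(buf$S[, 1], (n_push - cap + 1):n_push)

  # the function-level API agrees with the inlined path
  buf2 <- replay_buffer(3L, state_dim = 2L)
  for (i in 1:5) replay_push(buf2, c(i, i), i, i, c(i, i), FALSE)
  expect_identical(replay_size(buf2), 3L)
  expect_setequal(buf2$S[, 1], 3:5)
  set.seed(1)
  b <- replay_sample(buf2, 3L)
  expect_setequal(b$states[, 1], 3:5)      # without replacement
  expect_error(replay_sample(buf2, 4L), "sample")
})

test_that("td_update: non-negative loss, terminal fixed point,
           single-transition convergence", {
  net <- qnet_init(seed = 3)
  # zero all parameters: Q == 0 everywhere, so a terminal batch with r = 0
  # has target exactly equal to prediction -> loss 0
  zero <- net
  for (nm in names(zero)) zero[[nm]][] <- 0
  batch0 <- list(states = matrix(0, 4, 5), actions = c(0L, 5L, 100L, 200L),
                 rewards = rep(0, 4), next_states = matrix(0, 4, 5),
                 done = rep(TRUE, 4))
  expect_identical(td_update(zero, zero, batch0)$loss, 0)

  # random batches: loss is a mean of squares
  set.seed(8)
  batch <- list(states = matrix(rnorm(40), 8, 5), actions = sample(0:200, 8),
                rewards = runif(8, -1, 0),
                next_states = matrix(rnorm(40), 8, 5),
                done = rep(c(TRUE, FALSE), 4))
  expect_gte(td_update(net, net, batch)$loss, 0)

  # repeated updates on one terminal transition drive the loss to zero
  one <- list(states = matrix(c(0.1, -0.2, 0.3, 1, 0.5), 1, 5),
              actions = 42L, rewards = -0.3,
              next_states = matrix(0, 1, 5), done = TRUE)
  state <- NULL
  cur <- net
  loss <- Inf
  for (i in 1:5000) {
    up <- td_update(cur, cur, one, gamma = 0.95, lr = 1e-3,
                    opt_state = state)
    cur <- up$net
    state <- up$opt_state
    loss <- up$loss
    if (loss < 1e-4) break
  }
  expect_lt(loss, 1e-4)
})

test_that("training: epochs = 0, determinism, history shape", {
  s <- fix_session(dur = 30L, noise_sd = 1, seed = 2)
  cfg0 <- dqn_config(epochs = 0L, window_length_s = 60L,
                     train_stride_s = 60L)
  a0 <- train_dqn(list(s), cfg0)
  expect_identical(nrow(a0$history), 0L)
  expect_identical(a0$n_updates, 0)
  expect_error(train_dqn(list(), cfg0), "no training sessions")

  cfg <- dqn_config(epochs = 2L, window_length_s = 60L,
                    train_stride_s = 30L, warmup = 50L, seed = 31L)
  r1 <- train_dqn(list(s), cfg)
  r2 <- train_dqn(list(s), cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net, r2$net)
  expect_identical(nrow(r1$history), 2L)
  expect_true(all(is.finite(r1$history$loss)))
  expect_gt(r1$n_updates, 0)
  # a session shorter than the window is rejected
  expect_error(
    suppressWarnings(train_dqn(list(s), dqn_config(window_length_s = 500L))),
    "window_length_s")
})

test_that("prediction: length, bounds, hard-wired policy, causality of
           the output range", {
  s <- fix_session(dur = 40L, noise_sd = 1, seed = 12)
  agent <- fix_untrained_agent(s)
  pred <- predict_ee_series(agent, s)
  rmr <- session_rmr_sec(s)
  expect_length(pred, session_length(s))
  expect_true(all(pred >= rmr - 1e-12))
  expect_true(all(pred <= 21 * rmr + 1e-12))
  det <- predict_ee_series(agent, s, details = TRUE)
  expect_identical(det$pred_ee_kcal_s, pred)
  expect_true(all(det$action_index %in% 0:200))
  expect_close(det$a, det$action_index / 10, tol = 1e-12)

  # force the greedy argmax to index 0 via the output bias: every
  # prediction collapses to the resting rate
  wired <- agent
  wired$net$b3[] <- -1e6
  wired$net$b3[1] <- 1e6
  expect_close(predict_ee_series(wired, s), rep(rmr, session_length(s)),
               tol = 1e-12)
})

test_that("checkpoint round trip preserves behaviour", {
  dir <- withr::local_tempdir()
  s <- fix_session(dur = 30L, noise_sd = 1, seed = 4)
  agent <- train_dqn(list(s), dqn_config(epochs = 1L, window_length_s = 60L,
                                         train_stride_s = 60L, warmup = 20L,
                                         seed = 6L))
  f <- file.path(dir, "ckpt.json")
  save_agent(agent, f)
  back <- load_agent(f)
  expect_equal(back$net$W1, agent$net$W1, tolerance = 1e-12)
  expect_equal(back$scaler$center, unname(agent$scaler$center),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(predict_ee_series(back, s), predict_ee_series(agent, s),
               tolerance = 1e-12)
  expect_identical(back$config$window_length_s,
                   agent$config$window_length_s)
  # any other JSON is rejected as not-a-checkpoint
  write_session(s, file.path(dir, "x.csv"))
  expect_error(load_agent(file.path(dir, "x.json")), "checkpoint")
})
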