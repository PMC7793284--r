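# Contact initiation, timing, termination and the zombie-contact policy.

still_ctl_config <- function(...) {
  sim_config(N_T = 1, ...)
}

# a CTL that never moves, so geometry is fully controlled
frozen <- function(tgts, ...) {
  hand_arena(c(100, 100, 500), c(1, 0, 0), speed = 0, tgt_pos = tgts)
}

test_that("contacts start strictly below I_CF * (R_T + R_I) = 14.85 um", {
  cfg <- still_ctl_config(N_I = 1, T_Sim = 0.2, obs_end = 0.2)
  near <- frozen(matrix(c(114, 100, 500), 1))       # 14.0 um apart
  sim <- ctl_simulate(cfg, no_kill(), motility = straight_motility(0),
                      seed = 1, init = near)
  expect_equal(nrow(sim$events), 1L)
  expect_equal(sim$events$start_min, 0)

  far <- frozen(matrix(c(115, 100, 500), 1))        # 15.0 um apart
  sim2 <- ctl_simulate(cfg, no_kill(), motility = straight_motility(0),
                       seed = 1, init = far)
  expect_equal(nrow(sim2$events), 0L)
})

test_that("a CTL binds one target per tick, nearest first, ties by id", {
  cfg <- still_ctl_config(N_I = 3, T_Sim = 0.2, obs_end = 0.2)
  tgts <- matrix(c(112, 100, 500,    # 12 um
                   110, 100, 500,    # 10 um  <- nearest
                   100, 111, 500),   # 11 um
                 3, byrow = TRUE)
  sim <- ctl_simulate(cfg, no_kill(), motility = straight_motility(0),
                      seed = 1, init = frozen(tgts))
  first <- sim$events[which.min(sim$events$start_min), ]
  expect_equal(first$target_id, 2L)
  # monogamy: the single CTL never holds two open contacts
  expect_lte(sum(is.na(sim$events$end_min)), 1L)

  # exact tie broken by the lower target id
  tie <- matrix(c(110, 100, 500, 90, 100, 500), 2, byrow = TRUE)
  sim2 <- ctl_simulate(still_ctl_config(N_I = 2, T_Sim = 0.2,
                                        obs_end = 0.2),
                       no_kill(), motility = straight_motility(0),
                       seed = 1, init = frozen(tie))
  expect_equal(sim2$events$target_id[which.min(sim2$events$start_min)], 1L)
})

test_that("ending a contact triggers a refractory period of T_pers", {
  cfg <- still_ctl_config(N_I = 1, T_Sim = 20, obs_end = 20)
  sim <- ctl_simulate(cfg, no_kill(), motility = straight_motility(0),
                      duration = const_duration(0.5), seed = 2,
                      init = frozen(matrix(c(110, 100, 500), 1)))
  ev <- sim$events[order(sim$events$start_min), ]
  expect_gt(nrow(ev), 2)
  # CTL stays put (speed 0), target in range: re-initiation is delayed by
  # the 2-minute refractory period after each contact ends
  gaps <- ev$start_min[-1] - ev$end_min[-nrow(ev)]
  expect_true(all(gaps >= 2 - 1e-9))
  expect_true(all(gaps <= 2 + 0.1 + 1e-9))  # next tick after refractory
})

test_that("scheduled contact durations are honoured in the event log", {
  cfg <- still_ctl_config(N_I = 1, T_Sim = 60, obs_end = 60)
  sim <- ctl_simulate(cfg, no_kill(), motility = straight_motility(0),
                      seed = 3, init = frozen(matrix(c(110, 100, 500), 1)))
  done <- sim$events[sim$events$end_reason == "scheduled", ]
  expect_gt(nrow(done), 0)
  expect_equal(done$end_min - done$start_min, done$scheduled_min,
               tolerance = 1e-9)
  open_end <- sim$events[sim$events$end_reason == "window_end", ]
  expect_true(all(open_end$end_min == 60))
})

test_that("log-normal durations have the declared log-moments", {
  m <- contact_duration_model()
  expect_equal(m$log_mean, 2.1)
  expect_equal(m$log_sd, 1.2)
  set.seed(4)
  x <- sample_contact_duration(m, 1e5)
  expect_true(all(x > 0))
  expect_equal(mean(log(x)), 2.1, tolerance = 0.02 / 2.1)
  expect_equal(sd(log(x)), 1.2, tolerance = 0.02)
  truncated <- contact_duration_model(truncation_max = 40)
  y <- sample_contact_duration(truncated, 1e5)
  expect_true(all(y <= 40))
  expect_error(contact_duration_model(log_sd = 0), "log_sd")
})

test_that("a removed target ends its contacts early (whichever-first rule)", {
  # CTL 1 sits in range from t = 0; CTL 2 walks in and starts later. Both
  # contacts are scheduled for 30 min; certain death at the first contact
  # end with T_death = 0 removes the target at t = 30 and must cut the
  # staggered contact short.
  cfg <- sim_config(N_T = 2, N_I = 1, T_Sim = 120, obs_end = 120)
  ctls <- rbind(hand_arena(c(100, 100, 500), c(1, 0, 0), 0)$ctls,
                hand_arena(c(130, 100, 500), c(-1, 0, 0), 6)$ctls)
  ctls$id <- 1:2
  init <- list(ctls = ctls,
               targets = frozen(matrix(c(110, 100, 500), 1))$targets)
  hyp <- killing_hypothesis("null", p = 1, T_death = 0)
  sim <- ctl_simulate(cfg, hyp, motility = straight_motility(6),
                      duration = const_duration(30), seed = 5, init = init)
  tg <- sim$targets
  expect_equal(tg$state, "removed")
  expect_equal(tg$removal_min, 30, tolerance = 0.2)
  ev <- sim$events[order(sim$events$start_min), ]
  expect_equal(nrow(ev), 2L)
  expect_gt(ev$start_min[2], 0)          # the second contact started later
  cut <- sim$events[sim$events$end_reason == "target_removed", ]
  expect_equal(nrow(cut), 1L)
  expect_equal(cut$end_min, tg$removal_min, tolerance = 1e-9)
  expect_lt(cut$end_min - cut$start_min, cut$scheduled_min)
})

test_that("zombie contacts happen only when the policy allows them", {
  cfg <- small_config(T_Sim = 120, obs_end = 120)
  h_off <- killing_hypothesis("null", p = 0.5, T_death = 30)
  sim_off <- ctl_simulate(cfg, h_off, seed = 6)
  expect_true(all(sim_off$events$zombie == 0))

  h_on <- killing_hypothesis("null", p = 0.5, T_death = 30,
                             zombie_contacts = TRUE)
  sim_on <- ctl_simulate(cfg, h_on, seed = 6)
  # dying targets persist for 30 min and the seed gives plenty of kills,
  # so some new contacts start on dying cells
  expect_gt(sum(sim_on$events$zombie), 0)
  # zombie contacts never extend past the target's removal; on targets
  # still dying at the window end they are cut by the window instead
  zev <- sim_on$events[sim_on$events$zombie == 1, ]
  rem <- sim_on$targets$removal_min[zev$target_id]
  expect_true(all(zev$end_min[!is.na(rem)] <= rem[!is.na(rem)] + 1e-9))
  # targets still dying at the window end are never "removed" endings
  expect_true(all(zev$end_reason[is.na(rem)] %in%
                    c("scheduled", "window_end")))
})

test_that("removal follows the death decision by exactly T_death", {
  cfg <- small_config(T_Sim = 120, obs_end = 120)
  hyp <- killing_hypothesis("null", p = 0.3, T_death = 15)
  sim <- ctl_simulate(cfg, hyp, seed = 7)
  killed <- sim$targets[sim$targets$state == "removed", ]
  expect_gt(nrow(killed), 0)
  ends <- sim$events$end_min[sim$events$end_reason == "scheduled"]
  for (i in seq_len(nrow(killed))) {
    # some scheduled contact end sits exactly T_death before removal
    expect_true(any(abs(killed$removal_min[i] - 15 - ends) < 1e-6))
  }
})
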