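test_that("hypotheses validate their parameters and count them", {
  expect_error(killing_hypothesis("null"), "'p'")
  expect_error(killing_hypothesis("damage_repair", d = 0.03), "'r'")
  expect_error(killing_hypothesis("null", p = -0.1), "non-negative")
  k2 <- c("null", "infected_integration", "ctl_integration",
          "constant_damage", "ctl_integration_damage")
  args <- list(null = list(p = 0.2), infected_integration = list(k_I = 0.09),
               ctl_integration = list(k_T = 0.1),
               constant_damage = list(d = 0.03),
               ctl_integration_damage = list(k_T = 0.008),
               saturated_damage = list(d = 0.03, T_max = 20),
               damage_repair = list(d = 0.03, r = 0.009),
               ctl_heterogeneity = list(k_m = 0.18, k_s = 0.05),
               infected_heterogeneity = list(d_m = 0.1, d_s = 0.05))
  for (v in names(args)) {
    h <- do.call(killing_hypothesis,
                 c(list(variant = v, T_death = 15), args[[v]]))
    expect_equal(n_free_params(h), if (v %in% k2) 2L else 3L, info = v)
  }
})

test_that("contact-end kill probabilities follow the variant formulas", {
  ctl <- list(contacts = 3, kill_param = 0.4)
  tgt <- list(contacts = 3, susceptibility = 0.6)
  h <- function(...) killing_hypothesis(..., T_death = 15)
  expect_equal(contact_end_kill_probability(h("null", p = 0.2), ctl, tgt),
               0.2)
  expect_equal(contact_end_kill_probability(
    h("infected_integration", k_I = 0.09), ctl, tgt), 0.27)
  expect_equal(contact_end_kill_probability(
    h("infected_integration", k_I = 0.09), ctl,
    list(contacts = 12)), 1)  # 0.09 * 12 = 1.08 clamps
  expect_equal(contact_end_kill_probability(
    h("ctl_integration", k_T = 0.1), ctl, tgt), 0.3)
  expect_equal(contact_end_kill_probability(
    h("ctl_heterogeneity", k_m = 0.2, k_s = 0.1), ctl, tgt), 0.4)
  expect_equal(contact_end_kill_probability(
    h("infected_heterogeneity", d_m = 0.2, d_s = 0.1), ctl, tgt), 0.6)
  expect_error(contact_end_kill_probability(
    h("constant_damage", d = 0.03), ctl, tgt), "damage")
})

test_that("negative modulation makes kill probability non-increasing", {
  h <- killing_hypothesis("ctl_integration", k_T = 0.5, T_death = 15,
                          negative_modulation = TRUE)
  p <- vapply(1:10, function(ct)
    contact_end_kill_probability(h, list(contacts = ct), list()), numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_equal(p[1], 0.5)
  expect_equal(p[5], 0.1)
  # and all probabilities stay in [0, 1] across variants and counts
  for (ct in 0:30) {
    pos <- contact_end_kill_probability(
      killing_hypothesis("ctl_integration", k_T = 0.1, T_death = 0),
      list(contacts = ct), list())
    expect_true(pos >= 0 && pos <= 1)
  }
})

test_that("heterogeneity draws are clamped per-cell parameters", {
  cfg <- small_config()
  set.seed(8)
  arena <- build_arena(cfg)
  h0 <- killing_hypothesis("ctl_heterogeneity", k_m = 0.18, k_s = 0,
                           T_death = 30)
  out <- initialize_heterogeneity(h0, arena$ctls, arena$targets)
  expect_true(all(out$ctls$kill_param == 0.18))

  big <- build_arena(sim_config(N_T = 10000, N_I = 0, X_dim = 3000,
                                Y_dim = 3000, Z_dim = 3000))
  h1 <- killing_hypothesis("ctl_heterogeneity", k_m = 0.18, k_s = 0.05,
                           T_death = 30)
  out1 <- initialize_heterogeneity(h1, big$ctls, big$targets)
  expect_equal(mean(out1$ctls$kill_param), 0.18, tolerance = 0.002 / 0.18)
  expect_true(all(out1$ctls$kill_param >= 0 & out1$ctls$kill_param <= 1))

  h2 <- killing_hypothesis("infected_heterogeneity", d_m = 0.3, d_s = 0.05,
                           T_death = 15)
  out2 <- initialize_heterogeneity(h2, arena$ctls, arena$targets)
  expect_true(all(out2$targets$susceptibility >= 0 &
                    out2$targets$susceptibility <= 1))
  # no-op for other variants
  out3 <- initialize_heterogeneity(killing_hypothesis("null", p = 0.2),
                                   arena$ctls, arena$targets)
  expect_identical(out3$ctls, arena$ctls)
})

test_that("damage rates follow the variant differential equations", {
  two <- data.frame(start_min = c(0, 5), ctl_contacts = c(5, 2))
  h <- function(...) killing_hypothesis(..., T_death = 0)
  expect_equal(damage_rate_for_target(h("constant_damage", d = 0.03), two),
               0.06)
  # at t = 22 the contact from t = 0 has exceeded T_max, the one from
  # t = 5 has not
  expect_equal(damage_rate_for_target(
    h("saturated_damage", d = 0.03, T_max = 20), two, time = 22), 0.03)
  expect_equal(damage_rate_for_target(
    h("saturated_damage", d = 0.03, T_max = 20),
    data.frame(start_min = 0), time = 25), 0)
  expect_equal(damage_rate_for_target(
    h("ctl_integration_damage", k_T = 0.008),
    data.frame(start_min = 0, ctl_contacts = 5)), 0.04)
  expect_equal(damage_rate_for_target(h("damage_repair", d = 0.03,
                                        r = 0.009), two), 0.06)
  expect_equal(damage_rate_for_target(h("constant_damage", d = 0.03),
                                      two[0, ]), 0)
  expect_error(damage_rate_for_target(
    killing_hypothesis("null", p = 0.2), two), "probabilistic")
})

test_that("Euler damage steps accumulate, repair and trigger death", {
  hc <- killing_hypothesis("constant_damage", d = 0.03, T_death = 0)
  s <- apply_damage_step(list(damage = 0), rate = 0.06, hc, dt = 0.1)
  expect_equal(s$damage, 0.006)
  expect_false(s$death)
  hr <- killing_hypothesis("damage_repair", d = 0.03, r = 0.009,
                           T_death = 0)
  s2 <- apply_damage_step(list(damage = 0.5), rate = 0, hr, dt = 0.1)
  expect_equal(s2$damage, 0.49955)
  s3 <- apply_damage_step(list(damage = 0.999), rate = 0.03, hc, dt = 0.1)
  expect_equal(s3$damage, 1.002)
  expect_true(s3$death)
})

test_that("closed-form damage matches its limits and threshold root", {
  expect_equal(damage_closed_form_first_contact(0.03, 0.009, 0), 0)
  expect_equal(damage_closed_form_first_contact(0.03, 0.009, 1e9), 10 / 3)
  t_star <- time_to_complete_damage(0.03, 0.009)
  expect_equal(damage_closed_form_first_contact(0.03, 0.009, t_star), 1,
               tolerance = 1e-2)
  expect_error(damage_closed_form_first_contact(0.03, 0, 5), "positive")
})

test_that("time to the damage threshold matches the published magnitudes", {
  # without repair: 1/d ~ 33 minutes of accumulated contact
  expect_equal(time_to_complete_damage(0.03, 0), 100 / 3)
  # with repair at the fitted rates: roughly 40 minutes
  expect_equal(time_to_complete_damage(0.03, 0.009), 39.63, tolerance = 1e-3)
  # r -> 0 limit converges to 1/d
  expect_equal(time_to_complete_damage(0.03, 1e-8), 100 / 3,
               tolerance = 1e-6)
  expect_error(time_to_complete_damage(0.03, 0.03), "plateaus")
  expect_error(time_to_complete_damage(0.03, 0.05), "plateaus")
  expect_error(time_to_complete_damage(0, 0), "'d'")
})

test_that("Euler integration tracks the closed form within 0.5%", {
  hr <- killing_hypothesis("damage_repair", d = 0.03, r = 0.009,
                           T_death = 0)
  I <- 0
  for (step in seq_len(400)) {           # 40 minutes at dt = 0.1
    I <- apply_damage_step(list(damage = I), rate = 0.03, hr, 0.1)$damage
    t <- step * 0.1
    if (t >= 5) {
      exact <- damage_closed_form_first_contact(0.03, 0.009, t)
      expect_lt(abs(I - exact) / exact, 0.005)
    }
  }
})

test_that("the engine reproduces the single-contact damage closed form", {
  # one motionless CTL holding one long contact: the target must die when
  # integrated damage reaches 1, i.e. after ~39.6 min under repair
  cfg <- sim_config(N_T = 1, N_I = 1, T_Sim = 120, obs_end = 120)
  init <- hand_arena(c(100, 100, 500), c(1, 0, 0), 0,
                     tgt_pos = matrix(c(110, 100, 500), 1))
  hyp <- killing_hypothesis("damage_repair", d = 0.03, r = 0.009,
                            T_death = 0)
  sim <- ctl_simulate(cfg, hyp, motility = straight_motility(0),
                      duration = const_duration(100), seed = 10,
                      init = init)
  expect_equal(sim$targets$state, "removed")
  expect_equal(sim$targets$removal_min - sim$targets$first_contact_min,
               time_to_complete_damage(0.03, 0.009), tolerance = 0.01)
  # without repair the same setup dies after ~1/d minutes
  hyp0 <- killing_hypothesis("constant_damage", d = 0.03, T_death = 0)
  sim0 <- ctl_simulate(cfg, hyp0, motility = straight_motility(0),
                       duration = const_duration(100), seed = 10,
                       init = init)
  expect_equal(sim0$targets$removal_min - sim0$targets$first_contact_min,
               100 / 3, tolerance = 0.01)
})

test_that("saturated damage stops accruing after T_max per contact", {
  # one contact spanning the whole 60-min window (no re-initiation):
  # 1/d = 33.3 min > T_max = 20, so the single contact cannot kill
  cfg <- sim_config(N_T = 1, N_I = 1, T_Sim = 60, obs_end = 60)
  init <- hand_arena(c(100, 100, 500), c(1, 0, 0), 0,
                     tgt_pos = matrix(c(110, 100, 500), 1))
  hyp <- killing_hypothesis("saturated_damage", d = 0.03, T_max = 20,
                            T_death = 0)
  sim <- ctl_simulate(cfg, hyp, motility = straight_motility(0),
                      duration = const_duration(100), seed = 11,
                      init = init)
  expect_equal(sim$targets$state, "alive")
  expect_equal(sim$targets$damage, 0.03 * 20, tolerance = 0.01)
})

test_that("accumulated contact time, not wall-clock time, bounds killing", {
  # under constant damage with immediate removal every killed target must
  # have received at least 1/d contact-minutes, summed over (possibly
  # overlapping) contacts; wall-clock elimination can undercut 1/d only
  # through simultaneous contacts
  cfg <- sim_config()
  hyp <- killing_hypothesis("constant_damage", d = 0.03, T_death = 0)
  sim <- ctl_simulate(cfg, hyp, seed = 101)
  killed <- sim$targets[sim$targets$state == "removed", ]
  expect_gt(nrow(killed), 0)
  for (i in seq_len(nrow(killed))) {
    ev <- sim$events[sim$events$target_id == killed$id[i] &
                       sim$events$start_min < killed$removal_min[i], ]
    acc <- sum(pmin(ev$end_min, killed$removal_min[i]) - ev$start_min)
    # tick quantization: each contact contributes whole-dt damage quanta
    expect_gte(acc, 1 / 0.03 - (nrow(ev) + 1) * cfg$dt)
    # and clear wall-clock undercuts of 1/d (beyond tick quantization)
    # imply overlapping contacts
    t_elim <- killed$removal_min[i] - killed$first_contact_min[i]
    if (t_elim < 1 / 0.03 - 1) expect_gt(acc, t_elim)
  }
})
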