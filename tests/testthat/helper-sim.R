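# shared fixtures and helpers, all built in code at test time

# degenerate histograms pin speed / turning angle to a single value
const_hist <- function(value) binned_dist(c(value, value), 1)

# motility model that moves every CTL at `speed` and never turns
straight_motility <- function(speed) {
  motility_model(speed = const_hist(speed), turn = const_hist(0))
}

# near-deterministic contact durations of `minutes`
const_duration <- function(minutes) {
  contact_duration_model(log_mean = log(minutes), log_sd = 1e-9)
}

# hand-placed single-CTL arena: CTL at `ctl_pos` moving along `dir`,
# targets at rows of `tgt_pos`; persistence clock 0 so the first resample
# happens only after T_pers
hand_arena <- function(ctl_pos, dir, speed, tgt_pos = NULL) {
  dir <- dir / sqrt(sum(dir^2))
  ctls <- data.frame(id = 1L, x = ctl_pos[1], y = ctl_pos[2], z = ctl_pos[3],
                     dx = dir[1], dy = dir[2], dz = dir[3], speed = speed,
                     persistence_clock = 0, refractory_clock = 0,
                     bound_target = NA_integer_, contacts = 0L,
                     kill_param = NA_real_)
  n <- if (is.null(tgt_pos)) 0L else nrow(tgt_pos)
  targets <- data.frame(
    id = seq_len(n),
    x = if (n) tgt_pos[, 1] else numeric(0),
    y = if (n) tgt_pos[, 2] else numeric(0),
    z = if (n) tgt_pos[, 3] else numeric(0),
    state = rep("alive", n), damage = rep(0, n), contacts = rep(0L, n),
    susceptibility = rep(NA_real_, n),
    first_contact_min = rep(NA_real_, n), removal_min = rep(NA_real_, n),
    visible_from = rep(0, n))
  list(ctls = ctls, targets = targets)
}

# inert hypothesis: contacts happen but nothing ever dies
no_kill <- function(...) killing_hypothesis("null", p = 0, T_death = 0, ...)

# pooled observed kill probability by rank over replicate simulations
pooled_rank_curve <- function(sims, max_rank = 6L) {
  died <- at <- numeric(max_rank)
  for (s in sims) {
    rs <- compute_readouts(s, max_rank = max_rank)
    pr <- rs$kill_prob_by_rank
    ar <- attr(pr, "n_at_risk")
    died <- died + pr * ar
    at <- at + ar
  }
  list(prob = ifelse(at > 0, died / at, 0), died = died, at_risk = at)
}

# reduced arena for moderately fast whole-pipeline tests
small_config <- function(...) {
  args <- utils::modifyList(list(X_dim = 300, Y_dim = 300, Z_dim = 300,
                                 N_T = 40, N_I = 50), list(...))
  do.call(sim_config, args)
}
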