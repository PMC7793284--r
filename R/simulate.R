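#' Run one agent-based killing simulation
#'
#' Builds the arena, assigns any per-cell heterogeneity parameters, and
#' advances the model tick by tick for `T_Sim` minutes. Each tick of length
#' `dt` executes, in order: (a) free CTLs move by a persistent random walk
#' in a fresh random permutation, truncated at nuclear collisions and closed
#' z-boundaries (collisions resample the direction and forfeit the remaining
#' displacement); (b) free, non-refractory CTLs within
#' `I_CF * (R_T + R_I)` of an eligible target initiate a contact with a
#' log-normally distributed scheduled duration, halting the CTL; (c)
#' contacts whose scheduled time has elapsed end, freeing the CTL with a new
#' random direction, a fresh speed draw and a refractory period of `T_pers`,
#' and probabilistic variants take their Bernoulli death decision; (d)
#' damage variants integrate damage, death clocks advance, and targets whose
#' `T_death` delay has expired are removed, closing any remaining (zombie)
#' contacts on them.
#'
#' @param config a [sim_config()].
#' @param hypothesis a [killing_hypothesis()].
#' @param motility a [motility_model()].
#' @param duration a [contact_duration_model()].
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the run is fully reproducible.
#' @param audit record per-tick structural diagnostics (minimum nuclear
#'   separation, state counts, open contacts per CTL)? Adds an O(N^2) scan
#'   per tick.
#' @param init optional pre-built arena from [build_arena()] (after
#'   [initialize_heterogeneity()] if applicable); when supplied the arena is
#'   used as-is.
#' @param visible_from optional per-target times (minutes) before which a
#'   target is antigen-silent, i.e. invisible to CTL interaction (used by
#'   the priming scenario); defaults to 0 for all targets.
#' @param snapshot_interval minutes between arena snapshots recorded in the
#'   result's `snapshots` data frame (`time_min`, `cell_id`, `cell_type`,
#'   `x`, `y`, `z`, `state`), ready for `write.csv()`; 0 (the default)
#'   disables recording.
#' @return An object of class `ctl_sim`: a list with `events` (the contact
#'   log: `ctl_id`, `target_id`, `start_min`, `end_min`, `scheduled_min`,
#'   `zombie`, `end_reason`), `targets` (per-target fates: final `state`,
#'   contact count, damage, `first_contact_min`, `removal_min`), `ctls`
#'   (final contact counts and positions), the inputs, and optionally
#'   `audit`.
#' @examples
#' \donttest{
#' cfg <- sim_config(N_T = 40, N_I = 50, X_dim = 300, Y_dim = 300,
#'                   Z_dim = 300, T_Sim = 60, obs_end = 60)
#' hyp <- killing_hypothesis("null", p = 0.2, T_death = 15)
#' sim <- ctl_simulate(cfg, hyp, seed = 1)
#' summary(sim)
#' }
#' @export
ctl_simulate <- function(config, hypothesis,
                         motility = default_motility_model(),
                         duration = contact_duration_model(),
                         seed = NULL, audit = FALSE, init = NULL,
                         visible_from = NULL, snapshot_interval = 0) {
  stopifnot(inherits(config, "sim_config"),
            inherits(hypothesis, "killing_hypothesis"),
            inherits(motility, "motility_model"),
            inherits(duration, "contact_duration_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    init <- build_arena(config, motility)
    init <- initialize_heterogeneity(hypothesis, init$ctls, init$targets)
  }
  ctls <- init$ctls
  targets <- init$targets
  if (is.null(targets$visible_from)) targets$visible_from <- 0
  if (!is.null(visible_from)) {
    stopifnot(length(visible_from) == nrow(targets))
    targets$visible_from <- visible_from
  }

  raw <- run_engine_cpp(
    ctl_pos0 = as.matrix(ctls[, c("x", "y", "z")]),
    ctl_dir0 = as.matrix(ctls[, c("dx", "dy", "dz")]),
    ctl_speed0 = ctls$speed,
    pers_clock0 = ctls$persistence_clock,
    kill_param = ifelse(is.na(ctls$kill_param), 0, ctls$kill_param),
    tgt_pos0 = as.matrix(targets[, c("x", "y", "z")]),
    susceptibility = ifelse(is.na(targets$susceptibility), 0,
                            targets$susceptibility),
    visible_from = targets$visible_from,
    cfg = unclass(config),
    hyp = as_engine_hyp(hypothesis),
    motility = list(speed_edges = motility$speed$breaks,
                    speed_probs = motility$speed$probs,
                    turn_edges = motility$turn$breaks,
                    turn_probs = motility$turn$probs),
    durmod = unclass(duration),
    audit = audit, snapshot_interval = snapshot_interval)

  ev <- raw$events
  events <- data.frame(ctl_id = ev$ctl_id + 1L,
                       target_id = ev$target_id + 1L,
                       start_min = ev$start_min,
                       end_min = ev$end_min,
                       scheduled_min = ev$scheduled_min,
                       zombie = ev$zombie,
                       end_reason = ev$end_reason,
                       stringsAsFactors = FALSE)
  tg <- raw$targets
  fates <- data.frame(
    id = targets$id,
    state = c("alive", "dying", "removed")[tg$state + 1L],
    contacts = tg$contacts,
    damage = tg$damage,
    susceptibility = targets$susceptibility,
    first_contact_min = tg$first_contact_min,
    removal_min = tg$removal_min,
    x = targets$x, y = targets$y, z = targets$z,
    stringsAsFactors = FALSE)
  out <- list(events = events, targets = fates,
              ctls = data.frame(id = ctls$id, contacts = raw$ctls$contacts,
                                kill_param = ctls$kill_param,
                                x = raw$ctls$position[, 1],
                                y = raw$ctls$position[, 2],
                                z = raw$ctls$position[, 3]),
              config = config, hypothesis = hypothesis,
              motility = motility, duration = duration, seed = seed)
  if (audit) out$audit <- as.data.frame(raw$audit)
  if (snapshot_interval > 0) {
    sn <- as.data.frame(raw$snapshots)
    sn$cell_type <- c("ctl", "target")[sn$cell_type + 1L]
    sn$state <- c("free", "bound", "alive", "dying", "removed")[sn$state + 1L]
    out$snapshots <- sn
  }
  class(out) <- "ctl_sim"
  out
}

#' @export
print.ctl_sim <- function(x, ...) {
  nk <- sum(x$targets$state == "removed")
  cat(sprintf("CTL killing simulation: %d CTLs, %d targets, %g min\n",
              x$config$N_T, x$config$N_I, x$config$T_Sim))
  cat(sprintf("  hypothesis: %s%s\n", x$hypothesis$variant,
              if (x$hypothesis$zombie_contacts) " (+zombie contacts)" else ""))
  cat(sprintf("  contacts: %d (%d zombie); killed: %d of %d\n",
              nrow(x$events), sum(x$events$zombie), nk, x$config$N_I))
  invisible(x)
}

#' @export
summary.ctl_sim <- function(object, ...) {
  rs <- compute_readouts(object)
  st <- table(factor(object$targets$state,
                     levels = c("alive", "dying", "removed")))
  out <- list(states = st,
              n_contacts = nrow(object$events),
              n_zombie = sum(object$events$zombie),
              pckr = rs$pckr,
              fraction_killed = rs$fraction_killed,
              fraction_never_contacted = rs$fraction_never_contacted)
  class(out) <- "summary.ctl_sim"
  out
}

#' @export
print.summary.ctl_sim <- function(x, ...) {
  cat("Target fates: ", paste(names(x$states), as.integer(x$states),
                              sep = " = ", collapse = ", "), "\n")
  cat(sprintf("Contacts: %d (%d zombie)\n", x$n_contacts, x$n_zombie))
  cat(sprintf("PCKR: %.2f kills/CTL/24h; fraction killed %.3f; never contacted %.3f\n",
              x$pckr, x$fraction_killed, x$fraction_never_contacted))
  invisible(x)
}

#' Replicate simulations and collect readouts
#'
#' Runs `n_reps` independent simulations with replicate seeds derived
#' deterministically from the master seed and returns the readout set of
#' each replicate.
#'
#' @param config a [sim_config()].
#' @param hypothesis a [killing_hypothesis()].
#' @param n_reps number of replicates.
#' @param seed master seed; replicate `j` uses a seed derived from
#'   `(seed, stream, j)`.
#' @param motility,duration model inputs, as in [ctl_simulate()].
#' @param stream integer stream index separating seed families (used by the
#'   grid search to give every grid cell its own replicate seeds).
#' @param max_rank highest interaction rank in the kill-probability readout.
#' @return List of `n_reps` [compute_readouts()] results.
#' @export
replicate_readouts <- function(config, hypothesis, n_reps, seed,
                               motility = default_motility_model(),
                               duration = contact_duration_model(),
                               stream = 0L, max_rank = 6L) {
  lapply(seq_len(n_reps), function(j) {
    sim <- ctl_simulate(config, hypothesis, motility, duration,
                        seed = derive_seed(seed, stream, j))
    compute_readouts(sim, max_rank = max_rank)
  })
}
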