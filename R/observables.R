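#' Observed kill probability by interaction rank
#'
#' For each rank `i`, the number of targets that died at exactly their
#' `i`-th contact divided by the number of targets that experienced at
#' least `i` contacts. Empty denominators yield 0 and are flagged in the
#' `n_at_risk` attribute.
#'
#' @param n_contacts integer vector: observed contact count per target.
#' @param killed logical vector: was the target removed during the window?
#' @param max_rank highest rank reported.
#' @return Numeric vector of length `max_rank` with attribute `n_at_risk`.
#' @examples
#' kill_probability_by_rank(c(2, 3, 1, 1, 2),
#'                          c(TRUE, FALSE, TRUE, FALSE, FALSE), 3)
#' @export
kill_probability_by_rank <- function(n_contacts, killed, max_rank = 6L) {
  stopifnot(length(n_contacts) == length(killed))
  ranks <- seq_len(max_rank)
  at_risk <- vapply(ranks, function(i) sum(n_contacts >= i), integer(1))
  died_at <- vapply(ranks, function(i) sum(killed & n_contacts == i),
                    integer(1))
  prob <- ifelse(at_risk > 0, died_at / at_risk, 0)
  attr(prob, "n_at_risk") <- at_risk
  prob
}

# normalized histogram over given breaks; values above the top edge fall in
# the last bin, so the mass always sums to 1 when x is non-empty
normalized_hist <- function(x, breaks, denom = length(x)) {
  k <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = FALSE)
  k[k < 1L] <- 1L
  nb <- length(breaks) - 1L
  k[k > nb] <- nb
  counts <- tabulate(k, nbins = nb)
  binned_dist(breaks, if (denom > 0) counts / denom else counts * 0,
              normalized = FALSE)
}

#' Elimination-time distribution
#'
#' Histogram of `removal - first contact` over killed targets, normalized
#' by the number of killed targets with an observed first contact.
#'
#' @param first_contact,removal times in minutes, one entry per killed
#'   target.
#' @param breaks histogram bin edges in minutes.
#' @return A [binned_dist()] (unnormalized container; sums to 1 when any
#'   cell was killed).
#' @export
elimination_times <- function(first_contact, removal,
                              breaks = seq(0, 240, 10)) {
  ok <- is.finite(first_contact) & is.finite(removal)
  normalized_hist(removal[ok] - first_contact[ok], breaks)
}

#' Contact-count distributions by fate
#'
#' Unit-bin histograms of the per-target contact count, separately for
#' killed and surviving targets, each normalized by its population size.
#' The surviving histogram includes zero-contact cells.
#'
#' @param n_contacts integer vector of per-target contact counts.
#' @param killed logical vector.
#' @param max_count top count bin; larger counts are pooled into it.
#' @return `list(dead, alive)` of [binned_dist()] objects on unit bins
#'   `[-0.5, max_count + 0.5]`.
#' @export
contact_count_distributions <- function(n_contacts, killed,
                                        max_count = 30L) {
  breaks <- seq(-0.5, max_count + 0.5, 1)
  list(dead = normalized_hist(n_contacts[killed], breaks),
       alive = normalized_hist(n_contacts[!killed], breaks))
}

#' Contact-duration distributions by fate
#'
#' Computes, per target, the total time in contact with CTLs (summed over
#' contacts, so simultaneous contacts count multiply) and the individual
#' contact durations, split by target fate. Totals are normalized by the
#' population size; single durations by the population's contact count.
#'
#' @param events contact log restricted to the observation window, with
#'   columns `target_id`, `start_min`, `end_min`.
#' @param target_ids ids of all observed targets.
#' @param killed logical vector along `target_ids`.
#' @param breaks duration bin edges in minutes; durations beyond the top
#'   edge are pooled into the last bin.
#' @return `list(total_dead, total_alive, single_dead, single_alive)` of
#'   [binned_dist()] objects.
#' @export
contact_duration_distributions <- function(events, target_ids, killed,
                                           breaks = c(seq(0, 60, 5), Inf)) {
  dur <- events$end_min - events$start_min
  tot <- numeric(length(target_ids))
  if (nrow(events) > 0) {
    agg <- tapply(dur, events$target_id, sum)
    idx <- match(as.numeric(names(agg)), target_ids)
    tot[idx] <- as.numeric(agg)
  }
  ev_killed <- killed[match(events$target_id, target_ids)]
  list(total_dead = normalized_hist(tot[killed], breaks),
       total_alive = normalized_hist(tot[!killed], breaks),
       single_dead = normalized_hist(dur[ev_killed], breaks),
       single_alive = normalized_hist(dur[!ev_killed], breaks))
}

#' Per-capita killing rate
#'
#' Number of infected cells killed per CTL, linearly extrapolated to 24
#' hours.
#'
#' @param n_killed number of targets killed within the observation window.
#' @param n_ctl number of CTLs (must be positive).
#' @param obs_minutes length of the observation window in minutes.
#' @return Kills per CTL per 24 h.
#' @examples
#' pckr(40, 200, 240)  # 1.2
#' @export
pckr <- function(n_killed, n_ctl, obs_minutes) {
  if (n_ctl <= 0) stop("PCKR is undefined for n_ctl = 0", call. = FALSE)
  if (obs_minutes <= 0) stop("'obs_minutes' must be positive", call. = FALSE)
  (n_killed / n_ctl) * (1440 / obs_minutes)
}

#' Kill fraction and never-contacted fraction
#'
#' @param n_killed,n_never_contacted counts of targets.
#' @param n_initial initial number of infected cells.
#' @return A fraction in `[0, 1]`.
#' @export
fraction_killed <- function(n_killed, n_initial) {
  if (n_initial <= 0) stop("'n_initial' must be positive", call. = FALSE)
  n_killed / n_initial
}

#' @rdname fraction_killed
#' @export
fraction_never_contacted <- function(n_never_contacted, n_initial) {
  if (n_initial <= 0) stop("'n_initial' must be positive", call. = FALSE)
  n_never_contacted / n_initial
}

#' Compute the eight readout datasets from a simulation
#'
#' Applies the observation window and assembles the eight 2-photon-style
#' readouts used for fitting, plus the per-capita killing rate and kill
#' fractions: (1) observed kill probability by interaction rank, (2) the
#' elimination-time distribution (first contact to removal), (3, 4)
#' contact-count distributions for killed and surviving targets, (5, 6)
#' total and (7, 8) single contact-duration distributions by fate.
#'
#' Only contacts initiated inside `[obs_start, obs_end]` are observed;
#' open contacts are truncated at `obs_end`. Killed targets are those
#' removed inside the window; targets removed before `obs_start` are not
#' part of the observed population. Killed targets whose contacts all
#' predate `obs_start` count as zero-contact deaths.
#'
#' @param sim a [ctl_simulate()] result, or a list with `events`,
#'   `targets` and `config` entries.
#' @param obs_start,obs_end observation window, defaulting to the window in
#'   the simulation's configuration.
#' @param max_rank highest interaction rank in readout 1.
#' @param t_elim_breaks,dur_breaks,max_count bin specifications.
#' @return An object of class `readout_set`.
#' @export
compute_readouts <- function(sim, obs_start = NULL, obs_end = NULL,
                             max_rank = 6L, t_elim_breaks = NULL,
                             dur_breaks = c(seq(0, 60, 5), Inf),
                             max_count = 30L) {
  cfg <- sim$config
  if (is.null(obs_start)) obs_start <- cfg$obs_start
  if (is.null(obs_end)) obs_end <- cfg$obs_end
  if (is.null(t_elim_breaks)) t_elim_breaks <- seq(0, cfg$T_Sim, 10)
  ev <- sim$events
  tg <- sim$targets

  # observed population: targets not removed before the window opens
  obs <- is.na(tg$removal_min) | tg$removal_min >= obs_start
  tg <- tg[obs, , drop = FALSE]
  killed <- !is.na(tg$removal_min) & tg$removal_min <= obs_end

  # observed contacts: initiated inside the window, truncated at its end
  ev <- ev[ev$start_min >= obs_start & ev$start_min < obs_end, ,
           drop = FALSE]
  ev$end_min <- pmin(ev$end_min, obs_end)
  ev <- ev[ev$target_id %in% tg$id, , drop = FALSE]

  cnt <- integer(nrow(tg))
  if (nrow(ev) > 0) {
    tab <- table(ev$target_id)
    cnt[match(as.numeric(names(tab)), tg$id)] <- as.integer(tab)
  }
  first <- rep(NA_real_, nrow(tg))
  if (nrow(ev) > 0) {
    fc <- tapply(ev$start_min, ev$target_id, min)
    first[match(as.numeric(names(fc)), tg$id)] <- as.numeric(fc)
  }

  rank_prob <- kill_probability_by_rank(cnt, killed, max_rank)
  cc <- contact_count_distributions(cnt, killed, max_count)
  cd <- contact_duration_distributions(ev, tg$id, killed, dur_breaks)
  n_killed <- sum(killed)
  structure(list(
    kill_prob_by_rank = rank_prob,
    t_elim = elimination_times(first[killed], tg$removal_min[killed],
                               t_elim_breaks),
    n_contacts_dead = cc$dead,
    n_contacts_alive = cc$alive,
    total_dur_dead = cd$total_dead,
    total_dur_alive = cd$total_alive,
    single_dur_dead = cd$single_dead,
    single_dur_alive = cd$single_alive,
    pckr = if (cfg$N_T > 0) pckr(n_killed, cfg$N_T, obs_end - obs_start)
           else NA_real_,
    fraction_killed = fraction_killed(n_killed, cfg$N_I),
    fraction_never_contacted = fraction_never_contacted(sum(cnt == 0),
                                                        cfg$N_I),
    populations = c(n_dead = n_killed, n_alive = sum(!killed),
                    n_contacts = nrow(ev)),
    window = c(obs_start = obs_start, obs_end = obs_end)),
    class = "readout_set")
}

readout_dataset_names <- function() {
  c("kill_prob_by_rank", "t_elim", "n_contacts_dead", "n_contacts_alive",
    "total_dur_dead", "total_dur_alive", "single_dur_dead",
    "single_dur_alive")
}

# the eight datasets as plain numeric vectors (for cost computation)
readout_vectors <- function(rs) {
  lapply(stats::setNames(nm = readout_dataset_names()), function(nm) {
    v <- rs[[nm]]
    if (inherits(v, "binned_dist")) v$probs else as.numeric(v)
  })
}

#' @export
print.readout_set <- function(x, ...) {
  cat("Readout set (8 binned datasets)\n")
  cat(sprintf("  window [%g, %g] min; dead %d, alive %d, contacts %d\n",
              x$window[["obs_start"]], x$window[["obs_end"]],
              x$populations[["n_dead"]], x$populations[["n_alive"]],
              x$populations[["n_contacts"]]))
  cat(sprintf("  kill prob by rank: %s\n",
              paste(sprintf("%.3f", x$kill_prob_by_rank), collapse = " ")))
  cat(sprintf("  PCKR %.2f /CTL/24h; killed %.3f; never contacted %.3f\n",
              x$pckr, x$fraction_killed, x$fraction_never_contacted))
  invisible(x)
}
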