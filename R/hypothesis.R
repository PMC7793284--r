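#' Cell-death hypotheses
#'
#' Specifies which of the nine death-decision mechanisms governs target-cell
#' killing, its parameters, the delay `T_death` between the death decision
#' and the cell's visual removal, and whether CTLs may initiate new contacts
#' with already-dying targets ("zombie contacts").
#'
#' Probabilistic variants decide death by one Bernoulli draw at the end of
#' each (non-zombie) contact:
#' \describe{
#'   \item{`null`}{constant probability `p` per contact.}
#'   \item{`infected_integration`}{probability `k_I * C_I`, with `C_I` the
#'     target's accumulated contact count (including the current contact).}
#'   \item{`ctl_integration`}{probability `k_T * C_T` with `C_T` the CTL's
#'     accumulated contact count, or `k_T / C_T` when
#'     `negative_modulation = TRUE` (exhaustion).}
#'   \item{`ctl_heterogeneity`}{a fixed per-CTL probability drawn once from
#'     `Normal(k_m, k_s)`, clamped to `[0, 1]`.}
#'   \item{`infected_heterogeneity`}{a fixed per-target probability drawn
#'     once from `Normal(d_m, d_s)`, clamped to `[0, 1]`.}
#' }
#' Damage variants integrate damage `I` forward in time during contacts and
#' trigger death when `I >= 1`:
#' \describe{
#'   \item{`constant_damage`}{`dI/dt = n_CTL(t) * d`.}
#'   \item{`saturated_damage`}{as constant damage, but a contact stops
#'     damaging once its own elapsed time exceeds `T_max`.}
#'   \item{`damage_repair`}{`dI/dt = n_CTL(t) * d - r * I`.}
#'   \item{`ctl_integration_damage`}{`dI/dt = sum over engaged CTLs of
#'     k_T * C_T`.}
#' }
#'
#' @param variant one of `"null"`, `"infected_integration"`,
#'   `"ctl_integration"`, `"ctl_heterogeneity"`, `"infected_heterogeneity"`,
#'   `"constant_damage"`, `"saturated_damage"`, `"damage_repair"`,
#'   `"ctl_integration_damage"`.
#' @param p,k_I,k_T,k_m,k_s,d_m,d_s,d,r,T_max variant parameters (see
#'   Details); only the ones the variant uses must be supplied.
#' @param T_death minutes between the death decision and removal.
#' @param zombie_contacts allow new contacts with dying targets?
#' @param negative_modulation for `ctl_integration`: use `k_T / C_T`.
#' @return An object of class `killing_hypothesis`.
#' @examples
#' killing_hypothesis("null", p = 0.2, T_death = 15)
#' killing_hypothesis("damage_repair", d = 0.03, r = 0.009, T_death = 40)
#' @export
killing_hypothesis <- function(variant, p = NULL, k_I = NULL, k_T = NULL,
                               k_m = NULL, k_s = NULL, d_m = NULL,
                               d_s = NULL, d = NULL, r = NULL, T_max = NULL,
                               T_death = 0, zombie_contacts = FALSE,
                               negative_modulation = FALSE) {
  variants <- c("null", "infected_integration", "ctl_integration",
                "ctl_heterogeneity", "infected_heterogeneity",
                "constant_damage", "saturated_damage", "damage_repair",
                "ctl_integration_damage")
  variant <- match.arg(variant, variants)
  needed <- switch(variant,
    null = "p",
    infected_integration = "k_I",
    ctl_integration = "k_T",
    ctl_heterogeneity = c("k_m", "k_s"),
    infected_heterogeneity = c("d_m", "d_s"),
    constant_damage = "d",
    saturated_damage = c("d", "T_max"),
    damage_repair = c("d", "r"),
    ctl_integration_damage = "k_T")
  supplied <- list(p = p, k_I = k_I, k_T = k_T, k_m = k_m, k_s = k_s,
                   d_m = d_m, d_s = d_s, d = d, r = r, T_max = T_max)
  for (key in needed) {
    v <- supplied[[key]]
    if (is.null(v))
      stop("variant '", variant, "' requires parameter '", key, "'",
           call. = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", key, "' must be a single non-negative number",
           call. = FALSE)
  }
  if (!is.numeric(T_death) || length(T_death) != 1L || T_death < 0)
    stop("'T_death' must be a single non-negative number", call. = FALSE)
  params <- supplied[needed]
  structure(list(variant = variant,
                 variant_code = match(variant, variants),
                 params = params,
                 T_death = T_death,
                 zombie_contacts = isTRUE(zombie_contacts),
                 negative_modulation = isTRUE(negative_modulation)),
            class = "killing_hypothesis")
}

#' @export
print.killing_hypothesis <- function(x, ...) {
  pp <- paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
              collapse = ", ")
  cat(sprintf("Killing hypothesis '%s' (%s); T_death = %g min; zombie contacts %s\n",
              x$variant, pp, x$T_death,
              if (x$zombie_contacts) "on" else "off"))
  invisible(x)
}

is_probabilistic <- function(hyp) hyp$variant_code <= 5L
is_damage <- function(hyp) hyp$variant_code >= 6L

#' Number of free parameters of a hypothesis
#'
#' Counts the killing parameters of the variant plus one for `T_death`;
#' the zombie-contact flag is a model structure, not a fitted parameter.
#'
#' @param hyp a [killing_hypothesis()].
#' @return Integer: 2 for single-parameter variants, 3 for two-parameter
#'   ones.
#' @export
n_free_params <- function(hyp) {
  stopifnot(inherits(hyp, "killing_hypothesis"))
  length(hyp$params) + 1L
}

# engine-facing flat representation with every slot filled
as_engine_hyp <- function(hyp) {
  g <- function(key) if (is.null(hyp$params[[key]])) 0 else hyp$params[[key]]
  list(variant_code = hyp$variant_code,
       p = g("p"), k_I = g("k_I"), k_T = g("k_T"),
       d = g("d"), r = g("r"),
       T_max = if (is.null(hyp$params$T_max)) Inf else hyp$params$T_max,
       T_death = hyp$T_death,
       zombie_contacts = hyp$zombie_contacts,
       negative_modulation = hyp$negative_modulation)
}

#' Assign per-cell heterogeneity parameters
#'
#' For the `ctl_heterogeneity` variant each CTL receives an independent
#' killing probability drawn from `Normal(k_m, k_s)`; for
#' `infected_heterogeneity` each target receives a death probability from
#' `Normal(d_m, d_s)`. Draws are clamped to `[0, 1]` without redrawing.
#' For all other variants the cells are returned unchanged.
#'
#' @param hyp a [killing_hypothesis()].
#' @param ctls,targets cell data frames from [build_arena()].
#' @return `list(ctls, targets)` with `kill_param` / `susceptibility`
#'   filled in where applicable.
#' @export
initialize_heterogeneity <- function(hyp, ctls, targets) {
  stopifnot(inherits(hyp, "killing_hypothesis"))
  if (hyp$variant == "ctl_heterogeneity" && nrow(ctls) > 0) {
    ctls$kill_param <- pmin(1, pmax(0, stats::rnorm(
      nrow(ctls), hyp$params$k_m, hyp$params$k_s)))
  } else if (hyp$variant == "infected_heterogeneity" && nrow(targets) > 0) {
    targets$susceptibility <- pmin(1, pmax(0, stats::rnorm(
      nrow(targets), hyp$params$d_m, hyp$params$d_s)))
  }
  list(ctls = ctls, targets = targets)
}

#' Kill probability at the end of a contact
#'
#' Evaluates the death probability a probabilistic variant assigns to the
#' contact that just ended, clamped to `[0, 1]`. The contact counters are
#' taken as-is: both cells' counters were incremented when the contact was
#' initiated, so the current contact counts towards its own decision.
#'
#' @param hyp a probabilistic [killing_hypothesis()] (variants 1-5).
#' @param ctl list or one-row data frame with `contacts` (`C_T`) and, for
#'   the heterogeneity variant, `kill_param`.
#' @param target list or one-row data frame with `contacts` (`C_I`) and,
#'   for the heterogeneity variant, `susceptibility`.
#' @return A probability in `[0, 1]`.
#' @examples
#' h <- killing_hypothesis("infected_integration", k_I = 0.09, T_death = 15)
#' contact_end_kill_probability(h, list(contacts = 1),
#'                              list(contacts = 3))  # 0.27
#' @export
contact_end_kill_probability <- function(hyp, ctl, target) {
  stopifnot(inherits(hyp, "killing_hypothesis"))
  if (!is_probabilistic(hyp))
    stop("variant '", hyp$variant,
         "' is damage-based and takes no contact-end death decision",
         call. = FALSE)
  x <- switch(hyp$variant,
    null = hyp$params$p,
    infected_integration = hyp$params$k_I * target$contacts,
    ctl_integration = if (hyp$negative_modulation) {
      if (ctl$contacts > 0) hyp$params$k_T / ctl$contacts else 0
    } else hyp$params$k_T * ctl$contacts,
    ctl_heterogeneity = ctl$kill_param,
    infected_heterogeneity = target$susceptibility)
  min(1, max(0, x))
}

#' Damage rate on a target from its active contacts
#'
#' Evaluates `dI/dt` for the damage variants given the contacts currently
#' open on one target.
#'
#' @param hyp a damage [killing_hypothesis()] (variants 6-9).
#' @param contacts data frame of the target's open contacts with columns
#'   `start_min` and (for `ctl_integration_damage`) `ctl_contacts`, the
#'   engaged CTL's accumulated contact count.
#' @param time current time, minutes (used by `saturated_damage`).
#' @return Damage per minute.
#' @examples
#' h <- killing_hypothesis("constant_damage", d = 0.03, T_death = 35)
#' damage_rate_for_target(h, data.frame(start_min = c(0, 5)), time = 10)
#' @export
damage_rate_for_target <- function(hyp, contacts, time = 0) {
  stopifnot(inherits(hyp, "killing_hypothesis"))
  if (!is_damage(hyp))
    stop("variant '", hyp$variant,
         "' is probabilistic and accrues no damage", call. = FALSE)
  n <- nrow(contacts)
  if (is.null(n) || n == 0L) return(0)
  switch(hyp$variant,
    constant_damage = ,
    damage_repair = n * hyp$params$d,
    saturated_damage =
      hyp$params$d * sum(time - contacts$start_min < hyp$params$T_max),
    ctl_integration_damage =
      sum(hyp$params$k_T * contacts$ctl_contacts))
}

#' One forward-Euler damage step
#'
#' Updates a target's damage by `I <- I + rate * dt` (minus `r * I * dt`
#' under `damage_repair`), floors it at zero, and reports whether the death
#' threshold `I >= 1` was crossed.
#'
#' @param target list or one-row data frame with a `damage` entry.
#' @param rate damage rate per minute, from [damage_rate_for_target()].
#' @param hyp a damage [killing_hypothesis()].
#' @param dt time step, minutes.
#' @return `list(damage = updated damage, death = logical)`.
#' @export
apply_damage_step <- function(target, rate, hyp, dt) {
  stopifnot(inherits(hyp, "killing_hypothesis"), dt > 0)
  I <- target$damage + rate * dt
  if (hyp$variant == "damage_repair")
    I <- I - hyp$params$r * target$damage * dt
  I <- max(0, I)
  list(damage = I, death = I >= 1)
}

#' Damage during a single sustained contact, closed form
#'
#' Under damage rate `d` and repair rate `r > 0`, one uninterrupted contact
#' yields `I(t) = (d / r) * (1 - exp(-r t))`. Serves as the analytic oracle
#' for the forward-Euler integration.
#'
#' @param d damage rate per minute.
#' @param r repair rate per minute, strictly positive.
#' @param t contact time, minutes.
#' @return Damage level (dimensionless).
#' @export
damage_closed_form_first_contact <- function(d, r, t) {
  if (!is.numeric(r) || any(r <= 0))
    stop("'r' must be strictly positive (use d * t for the r = 0 limit)",
         call. = FALSE)
  (d / r) * (1 - exp(-r * t))
}

#' Single-contact time to reach the death threshold
#'
#' Minutes of one sustained contact needed for damage to reach 1:
#' `1 / d` without repair, and `-(1 / r) * log(1 - r / d)` under repair
#' rate `r`. Requires `r < d`; otherwise damage plateaus at `d / r <= 1`
#' and never reaches the threshold.
#'
#' @param d damage rate per minute, strictly positive.
#' @param r repair rate per minute, in `[0, d)`.
#' @return Minutes.
#' @examples
#' time_to_complete_damage(0.03, 0)      # 33.3 min
#' time_to_complete_damage(0.03, 0.009)  # ~39.6 min
#' @export
time_to_complete_damage <- function(d, r = 0) {
  if (!is.numeric(d) || d <= 0) stop("'d' must be positive", call. = FALSE)
  if (!is.numeric(r) || r < 0 || r >= d)
    stop("need 0 <= r < d: with r >= d damage plateaus at d/r <= 1 and the ",
         "threshold is never reached", call. = FALSE)
  if (r == 0) 1 / d else -(1 / r) * log(1 - r / d)
}
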