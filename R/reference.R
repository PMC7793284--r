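#' Generate self-consistent reference readouts
#'
#' The published experimental readout curves are available only as figure
#' panels, so the package generates synthetic reference readout sets by
#' running the simulator itself under a known hypothesis and averaging the
#' eight readouts over replicates. A provenance record (hypothesis,
#' parameters, seed) accompanies every reference so recovery analyses know
#' the ground truth.
#'
#' @param hypothesis the generating [killing_hypothesis()].
#' @param config a [sim_config()].
#' @param n_reps replicates averaged into the reference.
#' @param seed master seed.
#' @param dir optional directory; when given the reference is written there
#'   as TSV files plus `provenance.json` via [write_readout_set()].
#' @param motility,duration model inputs.
#' @param max_rank highest interaction rank in readout 1.
#' @return A `readout_set` (replicate average) with a `provenance`
#'   attribute.
#' @export
generate_reference_readouts <- function(hypothesis, config, n_reps = 30L,
                                        seed = 1L, dir = NULL,
                                        motility = default_motility_model(),
                                        duration = contact_duration_model(),
                                        max_rank = 6L) {
  reps <- replicate_readouts(config, hypothesis, n_reps, seed,
                             motility = motility, duration = duration,
                             max_rank = max_rank)
  ref <- average_readouts(reps)
  attr(ref, "provenance") <- list(
    generator = "ctlsim::generate_reference_readouts",
    synthetic = TRUE,
    hypothesis = list(variant = hypothesis$variant,
                      params = hypothesis$params,
                      T_death = hypothesis$T_death,
                      zombie_contacts = hypothesis$zombie_contacts),
    config = unclass(config), n_reps = n_reps, seed = seed,
    package_version = as.character(utils::packageVersion("ctlsim")))
  if (!is.null(dir)) write_readout_set(ref, dir)
  ref
}

#' Average readout sets over replicates
#'
#' Element-wise mean of the eight readout vectors and the scalar summaries.
#'
#' @param reps list of `readout_set`s sharing the same bin layout.
#' @return A `readout_set` holding the means.
#' @export
average_readouts <- function(reps) {
  stopifnot(length(reps) >= 1L)
  out <- reps[[1L]]
  for (nm in readout_dataset_names()) {
    vals <- lapply(reps, function(r)
      if (inherits(r[[nm]], "binned_dist")) r[[nm]]$probs
      else as.numeric(r[[nm]]))
    m <- Reduce(`+`, vals) / length(vals)
    if (inherits(out[[nm]], "binned_dist"))
      out[[nm]] <- binned_dist(out[[nm]]$breaks, m, normalized = FALSE)
    else {
      at <- attributes(out[[nm]])
      out[[nm]] <- m
      attr(out[[nm]], "n_at_risk") <-
        Reduce(`+`, lapply(reps, function(r) attr(r[[nm]], "n_at_risk"))) /
        length(reps)
    }
  }
  for (nm in c("pckr", "fraction_killed", "fraction_never_contacted"))
    out[[nm]] <- mean(vapply(reps, `[[`, numeric(1), nm))
  out$populations <- Reduce(`+`, lapply(reps, `[[`, "populations")) /
    length(reps)
  out
}

#' Write or read a readout set directory
#'
#' One TSV per dataset (`bin_left`, `bin_right`, `value`) plus
#' `summary.json` holding the scalar summaries (PCKR, kill fractions,
#' populations, window) and, when present, `provenance.json`.
#'
#' @param rs a `readout_set`.
#' @param dir directory path (created if missing).
#' @return `write_readout_set` returns `dir` invisibly; `read_readout_set`
#'   returns a `readout_set`.
#' @export
write_readout_set <- function(rs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in readout_dataset_names()) {
    v <- rs[[nm]]
    if (inherits(v, "binned_dist")) {
      n <- length(v$probs)
      d <- data.frame(bin_left = v$breaks[seq_len(n)],
                      bin_right = v$breaks[seq_len(n) + 1L],
                      value = v$probs)
    } else {
      ranks <- seq_along(v)
      d <- data.frame(bin_left = ranks - 0.5, bin_right = ranks + 0.5,
                      value = as.numeric(v))
    }
    utils::write.table(format(d, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(pckr = rs$pckr, fraction_killed = rs$fraction_killed,
         fraction_never_contacted = rs$fraction_never_contacted,
         populations = as.list(rs$populations),
         window = as.list(rs$window)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  prov <- attr(rs, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_readout_set
#' @export
read_readout_set <- function(dir) {
  rs <- list()
  for (nm in readout_dataset_names()) {
    d <- utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                           header = TRUE, sep = "\t")
    if (nm == "kill_prob_by_rank") {
      rs[[nm]] <- d$value
    } else {
      rs[[nm]] <- binned_dist(c(d$bin_left, d$bin_right[nrow(d)]), d$value,
                              normalized = FALSE)
    }
  }
  s <- jsonlite::read_json(file.path(dir, "summary.json"),
                           simplifyVector = TRUE)
  rs$pckr <- s$pckr
  rs$fraction_killed <- s$fraction_killed
  rs$fraction_never_contacted <- s$fraction_never_contacted
  rs$populations <- unlist(s$populations)
  rs$window <- unlist(s$window)
  class(rs) <- "readout_set"
  pj <- file.path(dir, "provenance.json")
  if (file.exists(pj))
    attr(rs, "provenance") <- jsonlite::read_json(pj, simplifyVector = TRUE)
  rs
}

#' Ready-made experiment scenarios
#'
#' Returns configuration bundles for the study's in silico experiments:
#' \describe{
#'   \item{`fig2` / `fig3`}{the default four-hour arena with the best-fit
#'     hypotheses in the absence (`fig2`) or presence (`fig3`) of zombie
#'     contacts.}
#'   \item{`fig4_vary_targets`}{`N_I` from 20 to 400 at `N_T = 200`, for
#'     per-capita killing rate and kill-fraction sweeps.}
#'   \item{`fig4_vary_ctls`}{`N_T` from 20 to 400 at `N_I = 250`.}
#'   \item{`priming`}{480-minute run with 500 targets of which 250 are
#'     antigen-silent (invisible to CTLs) for the first 240 minutes; the
#'     returned `visible_from` vector feeds [ctl_simulate()].}
#'   \item{`unknown_history`}{the default run observed only from 60
#'     minutes onward, discarding the first hour of model history.}
#' }
#'
#' @param name preset name.
#' @return A list with `name`, `configs` (list of [sim_config()]s) and,
#'   depending on the preset, `hypotheses` or `visible_from`.
#' @export
scenario_presets <- function(name) {
  presets <- c("fig2", "fig3", "fig4_vary_targets", "fig4_vary_ctls",
               "priming", "unknown_history")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: ", paste(presets, collapse = ", "),
         call. = FALSE)
  best_fit_hypotheses <- function(zombie) {
    if (!zombie) list(
      killing_hypothesis("infected_integration", k_I = 0.09, T_death = 15),
      killing_hypothesis("ctl_integration_damage", k_T = 0.008,
                         T_death = 10),
      killing_hypothesis("ctl_integration", k_T = 0.1, T_death = 20),
      killing_hypothesis("null", p = 0.2, T_death = 15),
      killing_hypothesis("constant_damage", d = 0.03, T_death = 35),
      killing_hypothesis("damage_repair", d = 0.03, r = 0.009,
                         T_death = 40),
      killing_hypothesis("saturated_damage", d = 0.03, T_max = 20,
                         T_death = 35),
      killing_hypothesis("ctl_heterogeneity", k_m = 0.18, k_s = 0.05,
                         T_death = 30),
      killing_hypothesis("infected_heterogeneity", d_m = 0.1, d_s = 0.05,
                         T_death = 15))
    else list(
      killing_hypothesis("ctl_integration", k_T = 0.14, T_death = 35,
                         zombie_contacts = TRUE),
      killing_hypothesis("infected_integration", k_I = 0.18, T_death = 35,
                         zombie_contacts = TRUE),
      killing_hypothesis("null", p = 0.35, T_death = 25,
                         zombie_contacts = TRUE),
      killing_hypothesis("ctl_integration_damage", k_T = 0.014,
                         T_death = 10, zombie_contacts = TRUE),
      killing_hypothesis("saturated_damage", d = 0.06, T_max = 10,
                         T_death = 15, zombie_contacts = TRUE),
      killing_hypothesis("constant_damage", d = 0.03, T_death = 35,
                         zombie_contacts = TRUE),
      killing_hypothesis("ctl_heterogeneity", k_m = 0.3, k_s = 0.05,
                         T_death = 30, zombie_contacts = TRUE),
      killing_hypothesis("damage_repair", d = 0.03, r = 0.009, T_death = 5,
                         zombie_contacts = TRUE),
      killing_hypothesis("infected_heterogeneity", d_m = 0.3, d_s = 0.05,
                         T_death = 15, zombie_contacts = TRUE))
  }
  switch(name,
    fig2 = list(name = name, configs = list(sim_config()),
                hypotheses = best_fit_hypotheses(FALSE)),
    fig3 = list(name = name, configs = list(sim_config()),
                hypotheses = best_fit_hypotheses(TRUE)),
    fig4_vary_targets = list(
      name = name,
      configs = lapply(c(20, 50, 100, 150, 200, 250, 300, 350, 400),
                       function(ni) sim_config(N_T = 200, N_I = ni))),
    fig4_vary_ctls = list(
      name = name,
      configs = lapply(c(20, 50, 100, 150, 200, 250, 300, 350, 400),
                       function(nt) sim_config(N_T = nt, N_I = 250))),
    priming = list(
      name = name,
      configs = list(sim_config(N_I = 500, T_Sim = 480, obs_end = 480)),
      visible_from = rep(c(0, 240), each = 250)),
    unknown_history = list(
      name = name,
      configs = list(sim_config(obs_start = 60))))
}
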