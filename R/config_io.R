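#' Parse a run configuration file
#'
#' Reads a YAML configuration describing one simulation run and resolves it
#' into the four model objects. Unspecified configuration fields fall back
#' to the defaults of [sim_config()]; the hypothesis section must name a
#' `variant` and supply its parameters. Histogram sections may either give
#' `breaks`/`probs` inline or a `file` path to a histogram TSV.
#'
#' Layout (all sections optional except `hypothesis`):
#' \preformatted{
#' config:      { N_T: 200, N_I: 250, T_Sim: 240, ... }
#' hypothesis:  { variant: null, p: 0.2, T_death: 15, zombie_contacts: no }
#' motility:
#'   speed: { file: speed.tsv }        # or breaks: [...], probs: [...]
#'   turn:  { breaks: [...], probs: [...] }
#' duration:    { log_mean: 2.1, log_sd: 1.2 }
#' }
#'
#' @param path YAML file path.
#' @return A list with `config`, `hypothesis`, `motility` and `duration`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) raw <- list()
  known <- c("config", "hypothesis", "motility", "duration")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown top-level key(s) in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)

  cfg_args <- raw$config
  if (!is.null(cfg_args)) {
    bad <- setdiff(names(cfg_args), names(formals(sim_config)))
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  config <- do.call(sim_config, as.list(cfg_args))

  hyp_args <- raw$hypothesis
  if (is.null(hyp_args) || is.null(hyp_args$variant))
    stop("the 'hypothesis' section must name a 'variant'", call. = FALSE)
  bad <- setdiff(names(hyp_args), names(formals(killing_hypothesis)))
  if (length(bad) > 0)
    stop("unknown hypothesis key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  hypothesis <- do.call(killing_hypothesis, as.list(hyp_args))

  read_hist <- function(spec, default) {
    if (is.null(spec)) return(default)
    if (!is.null(spec$file))
      read_histogram_tsv(if (file.exists(spec$file)) spec$file
                         else file.path(dirname(path), spec$file))
    else binned_dist(unlist(spec$breaks), unlist(spec$probs))
  }
  def <- default_motility_model()
  motility <- motility_model(read_hist(raw$motility$speed, def$speed),
                             read_hist(raw$motility$turn, def$turn))
  dur_args <- raw$duration
  if (!is.null(dur_args)) {
    bad <- setdiff(names(dur_args), names(formals(contact_duration_model)))
    if (length(bad) > 0)
      stop("unknown duration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  duration <- do.call(contact_duration_model, as.list(dur_args))
  list(config = config, hypothesis = hypothesis, motility = motility,
       duration = duration)
}

#' Write a run configuration file
#'
#' Serializes the four model objects back to the YAML layout understood by
#' [parse_config()], with motility histograms inlined.
#'
#' @param config a [sim_config()].
#' @param hypothesis a [killing_hypothesis()].
#' @param motility a [motility_model()].
#' @param duration a [contact_duration_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, hypothesis, motility, duration, path) {
  hyp <- c(list(variant = hypothesis$variant), hypothesis$params,
           list(T_death = hypothesis$T_death,
                zombie_contacts = hypothesis$zombie_contacts,
                negative_modulation = hypothesis$negative_modulation))
  out <- list(
    config = unclass(config),
    hypothesis = hyp,
    motility = list(
      speed = list(breaks = motility$speed$breaks,
                   probs = motility$speed$probs),
      turn = list(breaks = motility$turn$breaks,
                  probs = motility$turn$probs)),
    duration = list(log_mean = duration$log_mean, log_sd = duration$log_sd,
                    truncation_max = if (is.finite(duration$truncation_max))
                      duration$truncation_max else NULL))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
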