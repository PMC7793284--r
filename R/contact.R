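#' Contact-duration model
#'
#' CTL/target contact durations are drawn from a log-normal distribution:
#' `exp(Normal(log_mean, log_sd))` minutes. The defaults (2.1 and 1.2 in
#' log-minutes, median about 8.2 min) describe the fitted in vivo contact
#' durations. An optional truncation rejects and redraws values above
#' `truncation_max`.
#'
#' @param log_mean mean of the log-durations (log-minutes).
#' @param log_sd standard deviation of the log-durations, strictly positive.
#' @param truncation_max upper truncation in minutes, or `Inf` for none.
#' @return An object of class `contact_duration_model`.
#' @export
contact_duration_model <- function(log_mean = 2.1, log_sd = 1.2,
                                   truncation_max = Inf) {
  if (!is.numeric(log_sd) || log_sd <= 0)
    stop("'log_sd' must be strictly positive", call. = FALSE)
  if (!is.numeric(truncation_max) || truncation_max <= 0)
    stop("'truncation_max' must be positive (Inf for none)", call. = FALSE)
  structure(list(log_mean = log_mean, log_sd = log_sd,
                 truncation_max = truncation_max),
            class = "contact_duration_model")
}

#' @export
print.contact_duration_model <- function(x, ...) {
  cat(sprintf(
    "Log-normal contact durations: log-mean %g, log-sd %g (median %.2f min)%s\n",
    x$log_mean, x$log_sd, exp(x$log_mean),
    if (is.finite(x$truncation_max))
      sprintf(", truncated at %g min", x$truncation_max) else ""))
  invisible(x)
}

#' Sample contact durations
#'
#' @param model a [contact_duration_model()].
#' @param n number of draws.
#' @return Strictly positive durations in minutes.
#' @examples
#' m <- contact_duration_model()
#' mean(log(sample_contact_duration(m, 1e4)))  # about 2.1
#' @export
sample_contact_duration <- function(model, n = 1L) {
  stopifnot(inherits(model, "contact_duration_model"))
  out <- stats::rlnorm(n, model$log_mean, model$log_sd)
  while (any(bad <- out > model$truncation_max))
    out[bad] <- stats::rlnorm(sum(bad), model$log_mean, model$log_sd)
  out
}
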