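#' Simulation configuration
#'
#' Builds and validates the arena and scheduling parameters of the
#' agent-based model. Defaults describe a 700 x 700 x 700 micrometre block of
#' lymph-node tissue imaged over four hours: 200 cytotoxic T lymphocytes
#' (CTLs) patrol the full volume while 250 stationary infected cells occupy
#' the top 40\% of the z-axis, mirroring the limited imaging depth of
#' intravital 2-photon microscopy.
#'
#' The x- and y-boundaries are periodic; the z-boundaries are closed. Nuclear
#' hard-core repulsion acts at `C_CF * (r_a + r_b)` between cell centres and
#' interactions are initiated below `I_CF * (R_T + R_I)`, the larger
#' interaction radius accounting for pseudopodial reach.
#'
#' @param X_dim,Y_dim,Z_dim arena edge lengths, micrometres.
#' @param Z_lim fraction of the z-axis (measured from the top) in which
#'   infected cells are placed; in `(0, 1]`.
#' @param N_T,N_I number of CTLs and infected cells.
#' @param R_T,R_I cell radii, micrometres.
#' @param I_CF interaction confinement factor (>= 1).
#' @param C_CF collision (nucleus) confinement factor (in `(0, 1]`).
#' @param T_pers persistence time of the random walk, minutes; also the
#'   refractory period after a contact ends.
#' @param dt time step, minutes.
#' @param T_Sim total simulated time, minutes.
#' @param obs_start,obs_end observation window for readout computation,
#'   minutes.
#' @param n_reps default number of replicate simulations.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config()
#' cfg$N_T
#' sim_config(N_I = 100, T_Sim = 120)
#' @export
sim_config <- function(X_dim = 700, Y_dim = 700, Z_dim = 700, Z_lim = 0.4,
                       N_T = 200, N_I = 250, R_T = 4.8, R_I = 5.1,
                       I_CF = 1.5, C_CF = 0.5, T_pers = 2, dt = 0.1,
                       T_Sim = 240, obs_start = 0, obs_end = T_Sim,
                       n_reps = 30) {
  cfg <- list(X_dim = X_dim, Y_dim = Y_dim, Z_dim = Z_dim, Z_lim = Z_lim,
              N_T = as.integer(N_T), N_I = as.integer(N_I),
              R_T = R_T, R_I = R_I, I_CF = I_CF, C_CF = C_CF,
              T_pers = T_pers, dt = dt, T_Sim = T_Sim,
              obs_start = obs_start, obs_end = obs_end,
              n_reps = as.integer(n_reps))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num1 <- function(key, positive = TRUE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", key, "' must be a single finite number", call. = FALSE)
    if (positive && v <= 0)
      stop("'", key, "' must be strictly positive", call. = FALSE)
    invisible(v)
  }
  for (k in c("X_dim", "Y_dim", "Z_dim", "R_T", "R_I", "T_pers", "dt",
              "T_Sim"))
    num1(k)
  num1("Z_lim")
  if (cfg$Z_lim > 1) stop("'Z_lim' must be in (0, 1]", call. = FALSE)
  if (cfg$C_CF <= 0 || cfg$C_CF > 1)
    stop("'C_CF' must be in (0, 1]", call. = FALSE)
  if (cfg$I_CF < 1)
    stop("'I_CF' must be >= 1", call. = FALSE)
  if (cfg$N_T < 0 || cfg$N_I < 0)
    stop("cell counts 'N_T' and 'N_I' must be non-negative", call. = FALSE)
  if (cfg$obs_start < 0 || cfg$obs_end <= cfg$obs_start)
    stop("observation window requires 0 <= obs_start < obs_end",
         call. = FALSE)
  if (cfg$obs_end > cfg$T_Sim)
    stop("'obs_end' cannot exceed 'T_Sim'", call. = FALSE)
  if (cfg$n_reps < 1) stop("'n_reps' must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  arena: %g x %g x %g um, infected cells in top %g%% of z\n",
              x$X_dim, x$Y_dim, x$Z_dim, 100 * x$Z_lim))
  cat(sprintf("  cells: %d CTLs (R = %g um), %d infected (R = %g um)\n",
              x$N_T, x$R_T, x$N_I, x$R_I))
  cat(sprintf("  factors: I_CF = %g, C_CF = %g; T_pers = %g min\n",
              x$I_CF, x$C_CF, x$T_pers))
  cat(sprintf("  time: dt = %g min, T_Sim = %g min, observed [%g, %g] min\n",
              x$dt, x$T_Sim, x$obs_start, x$obs_end))
  invisible(x)
}

# replicate seeds derived deterministically from a master seed; kept
# within the 32-bit integer range expected by set.seed()
derive_seed <- function(master, i, j = 0L) {
  m <- as.double(master) %% 2147483647
  as.integer((m * 1103 + as.double(i) * 97561 + as.double(j) * 7919 + 1) %%
               2147483647)
}
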