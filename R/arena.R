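#' Place cells in the arena
#'
#' Draws initial positions for all cells: CTLs uniformly in the full arena,
#' infected cells uniformly in the top `Z_lim` fraction of the z-axis. No two
#' nuclei may overlap, i.e. every pair of centres keeps a distance of at
#' least `C_CF * (r_a + r_b)` under the periodic x/y metric. Each CTL
#' receives an initial speed drawn from the speed histogram, a uniformly
#' random unit direction, and a persistence clock uniform in `[0, T_pers)`
#' so direction changes are desynchronized from the start.
#'
#' Placement uses bounded rejection sampling; if the arena is too dense the
#' function fails with an error naming the constraint that could not be
#' satisfied.
#'
#' @param config a [sim_config()].
#' @param motility a [motility_model()].
#' @param max_retries total rejection-sampling budget.
#' @return A list with data frames `ctls` and `targets`.
#' @examples
#' set.seed(1)
#' arena <- build_arena(sim_config(N_T = 20, N_I = 25))
#' range(arena$targets$z)  # top 40% of the z-axis
#' @export
build_arena <- function(config, motility = default_motility_model(),
                        max_retries = 1e5) {
  stopifnot(inherits(config, "sim_config"),
            inherits(motility, "motility_model"))
  n_tot <- config$N_T + config$N_I
  px <- numeric(n_tot); py <- numeric(n_tot); pz <- numeric(n_tot)
  rad <- c(rep(config$R_T, config$N_T), rep(config$R_I, config$N_I))
  z_floor <- (1 - config$Z_lim) * config$Z_dim
  retries <- 0L
  for (i in seq_len(n_tot)) {
    is_target <- i > config$N_T
    repeat {
      cx <- stats::runif(1, 0, config$X_dim)
      cy <- stats::runif(1, 0, config$Y_dim)
      cz <- if (is_target) stats::runif(1, z_floor, config$Z_dim)
            else stats::runif(1, 0, config$Z_dim)
      ok <- TRUE
      if (i > 1L) {
        j <- seq_len(i - 1L)
        dx <- pmin(abs(px[j] - cx), config$X_dim - abs(px[j] - cx))
        dy <- pmin(abs(py[j] - cy), config$Y_dim - abs(py[j] - cy))
        dz <- pz[j] - cz
        ok <- all(dx * dx + dy * dy + dz * dz >=
                    (config$C_CF * (rad[j] + rad[i]))^2)
      }
      if (ok) { px[i] <- cx; py[i] <- cy; pz[i] <- cz; break }
      retries <- retries + 1L
      if (retries >= max_retries) {
        stop(sprintf(paste0(
          "could not place cell %d of %d after %d rejections: the %s ",
          "placement region is too dense for non-overlapping nuclei ",
          "(C_CF * (r_a + r_b) spacing); reduce cell numbers or enlarge ",
          "the arena"),
          i, n_tot, retries,
          if (is_target) "infected-cell (top Z_lim slab)" else "CTL"),
          call. = FALSE)
      }
    }
  }
  it <- seq_len(config$N_T)
  dir <- matrix(stats::rnorm(3 * config$N_T), ncol = 3)
  if (config$N_T > 0) {
    nrm <- sqrt(rowSums(dir^2))
    nrm[nrm < 1e-12] <- 1
    dir <- dir / nrm
  }
  nT <- config$N_T
  ctls <- data.frame(
    id = it,
    x = px[it], y = py[it], z = pz[it],
    dx = dir[seq_len(nT), 1], dy = dir[seq_len(nT), 2],
    dz = dir[seq_len(nT), 3],
    speed = if (nT > 0) sample_from_histogram(motility$speed, nT)
            else numeric(0),
    persistence_clock = stats::runif(nT, 0, config$T_pers),
    refractory_clock = rep(0, nT),
    bound_target = rep(NA_integer_, nT),
    contacts = rep(0L, nT),
    kill_param = rep(NA_real_, nT))
  nI <- config$N_I
  jt <- nT + seq_len(nI)
  targets <- data.frame(
    id = seq_len(nI),
    x = px[jt], y = py[jt], z = pz[jt],
    state = rep("alive", nI),
    damage = rep(0, nI),
    contacts = rep(0L, nI),
    susceptibility = rep(NA_real_, nI),
    first_contact_min = rep(NA_real_, nI),
    removal_min = rep(NA_real_, nI),
    visible_from = rep(0, nI))
  list(ctls = ctls, targets = targets)
}
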