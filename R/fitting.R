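#' Cost of one readout dataset
#'
#' Mean over replicate simulations of the sum of squared deviations between
#' the reference vector and each replicate's vector. Vectors of unequal
#' length are right-padded with zeros before comparison.
#'
#' @param reference numeric reference vector.
#' @param replicates list of numeric vectors, one per replicate simulation.
#' @return Non-negative cost.
#' @examples
#' dataset_cost(c(0.1, 0.2), list(c(0.1, 0.4)))  # 0.04
#' @export
dataset_cost <- function(reference, replicates) {
  if (!is.list(replicates) || length(replicates) == 0L)
    stop("need at least one replicate vector", call. = FALSE)
  sse <- vapply(replicates, function(m) {
    n <- max(length(reference), length(m))
    e <- c(reference, rep(0, n - length(reference)))
    m <- c(m, rep(0, n - length(m)))
    sum((e - m)^2)
  }, numeric(1))
  mean(sse)
}

#' Mean cost over the eight datasets
#'
#' @param cx numeric vector of exactly eight per-dataset costs.
#' @return Their arithmetic mean.
#' @export
mean_cost <- function(cx) {
  if (length(cx) != 8L)
    stop("expected exactly 8 per-dataset costs, got ", length(cx),
         call. = FALSE)
  mean(cx)
}

#' AIC from mean cost and parameter count
#'
#' Model-selection score `N * log(C) + 2k` over the `N = 8` readout
#' datasets, where `C` is the mean cost and `k` the number of free
#' parameters of the hypothesis (its killing parameters plus `T_death`).
#' Lower is better.
#'
#' @param C mean cost, strictly positive.
#' @param k number of free parameters, at least 1.
#' @param n_datasets number of datasets entering the mean cost.
#' @return The AIC value.
#' @examples
#' aic_score(4.35e-3, 2)  # -39.5
#' @export
aic_score <- function(C, k, n_datasets = 8L) {
  if (!is.numeric(C) || any(C <= 0))
    stop("mean cost 'C' must be strictly positive", call. = FALSE)
  if (any(k < 1)) stop("'k' must be >= 1", call. = FALSE)
  n_datasets * log(C) + 2 * k
}

#' Score a hypothesis against a reference readout set
#'
#' Computes the eight per-dataset costs of replicate simulations against a
#' reference, their mean, and the AIC. For the kill-probability-by-rank
#' dataset only the first six interaction ranks enter the cost.
#'
#' @param hypothesis the [killing_hypothesis()] that generated the
#'   replicates.
#' @param reference a `readout_set` (simulated reference or one read from
#'   disk via [read_readout_set()]).
#' @param replicates list of `readout_set`s from [replicate_readouts()].
#' @param cost_ranks ranks of readout 1 included in the cost.
#' @return An object of class `cost_result` with elements `C_x` (named,
#'   length 8), `cost`, `k`, `aic`, `n_reps` and `hypothesis`.
#' @export
score_hypothesis <- function(hypothesis, reference, replicates,
                             cost_ranks = 1:6) {
  stopifnot(inherits(hypothesis, "killing_hypothesis"))
  ref_v <- readout_vectors(reference)
  rep_v <- lapply(replicates, readout_vectors)
  cx <- vapply(readout_dataset_names(), function(nm) {
    ref <- ref_v[[nm]]
    reps <- lapply(rep_v, `[[`, nm)
    if (nm == "kill_prob_by_rank") {
      ref <- ref[cost_ranks]
      reps <- lapply(reps, function(v) v[cost_ranks])
    }
    dataset_cost(ref, reps)
  }, numeric(1))
  C <- mean_cost(cx)
  k <- n_free_params(hypothesis)
  structure(list(hypothesis = hypothesis, C_x = cx, cost = C, k = k,
                 aic = aic_score(C, k), n_reps = length(replicates)),
            class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("Hypothesis '%s'%s: mean cost %.4g (k = %d, %d reps), AIC %.1f\n",
              x$hypothesis$variant,
              if (x$hypothesis$zombie_contacts) " +zombies" else "",
              x$cost, x$k, x$n_reps, x$aic))
  invisible(x)
}

#' Fit a killing hypothesis by exhaustive grid search
#'
#' For every parameter combination in `grid`, runs `n_reps` replicate
#' simulations (with seeds derived deterministically from `seed`, the grid
#' row and the replicate index), scores them against the reference readouts,
#' and returns the full cost surface together with the best-fitting
#' parameter set. Ties are broken by smaller `T_death`, then by smaller
#' first killing parameter.
#'
#' @param variant hypothesis variant name, see [killing_hypothesis()].
#' @param grid data frame; one column per hypothesis parameter (e.g. `p`
#'   and `T_death` for the null variant), one row per grid point.
#' @param reference `readout_set` to fit against.
#' @param config a [sim_config()].
#' @param n_reps replicate simulations per grid point.
#' @param seed master seed for the search.
#' @param zombie_contacts model structure flag passed to every hypothesis.
#' @param motility,duration model inputs.
#' @param cost_ranks ranks of the kill-probability readout entering the
#'   cost.
#' @return An object of class `ctl_fit` with the cost `surface` (one row
#'   per grid point: parameters, `C_1` ... `C_8`, `cost`, `aic`), the
#'   index of the best row, the best [killing_hypothesis()], and the call.
#'   Supports `print()`, `summary()`, `coef()`, `plot()` and `simulate()`.
#' @examples
#' \donttest{
#' cfg <- sim_config(N_T = 30, N_I = 40, X_dim = 300, Y_dim = 300,
#'                   Z_dim = 300, T_Sim = 90, obs_end = 90)
#' truth <- killing_hypothesis("null", p = 0.2, T_death = 15)
#' ref <- generate_reference_readouts(truth, cfg, n_reps = 3, seed = 7)
#' fit <- ctl_fit("null", expand.grid(p = c(0.1, 0.2, 0.3),
#'                                    T_death = c(5, 15, 25)),
#'                ref, cfg, n_reps = 3, seed = 11)
#' coef(fit)
#' }
#' @export
ctl_fit <- function(variant, grid, reference, config, n_reps = 10L,
                    seed = 1L, zombie_contacts = FALSE,
                    motility = default_motility_model(),
                    duration = contact_duration_model(),
                    cost_ranks = 1:6) {
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop("'grid' must be a non-empty data frame of parameter combinations",
         call. = FALSE)
  if (n_reps < 1L) stop("'n_reps' must be >= 1", call. = FALSE)
  results <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    args <- c(list(variant = variant, zombie_contacts = zombie_contacts),
              as.list(grid[g, , drop = FALSE]))
    hyp <- do.call(killing_hypothesis, args)
    reps <- replicate_readouts(config, hyp, n_reps, seed,
                               motility = motility, duration = duration,
                               stream = g)
    results[[g]] <- score_hypothesis(hyp, reference, reps, cost_ranks)
  }
  cx <- t(vapply(results, `[[`, numeric(8), "C_x"))
  colnames(cx) <- paste0("C_", 1:8)
  surface <- cbind(grid,
                   as.data.frame(cx),
                   cost = vapply(results, `[[`, numeric(1), "cost"),
                   aic = vapply(results, `[[`, numeric(1), "aic"))
  # argmin with deterministic tie-breaking
  ord_cols <- list(surface$cost)
  if ("T_death" %in% names(grid)) ord_cols <- c(ord_cols,
                                                list(surface$T_death))
  kill_cols <- setdiff(names(grid), "T_death")
  if (length(kill_cols) > 0)
    ord_cols <- c(ord_cols, list(surface[[kill_cols[1L]]]))
  best <- do.call(order, ord_cols)[1L]
  structure(list(surface = surface, best = best,
                 best_hypothesis = results[[best]]$hypothesis,
                 best_result = results[[best]],
                 variant = variant, grid = grid, reference = reference,
                 config = config, n_reps = as.integer(n_reps),
                 seed = as.integer(seed),
                 zombie_contacts = zombie_contacts,
                 motility = motility, duration = duration,
                 call = match.call()),
            class = "ctl_fit")
}

#' @export
print.ctl_fit <- function(x, ...) {
  cat(sprintf("Grid-search fit of '%s'%s over %d parameter sets (%d reps each)\n",
              x$variant, if (x$zombie_contacts) " +zombies" else "",
              nrow(x$surface), x$n_reps))
  cat("Best parameters:\n")
  print(coef(x))
  cat(sprintf("cost %.4g, AIC %.1f\n", x$surface$cost[x$best],
              x$surface$aic[x$best]))
  invisible(x)
}

#' @export
coef.ctl_fit <- function(object, ...) {
  unlist(object$grid[object$best, , drop = FALSE])
}

#' @export
summary.ctl_fit <- function(object, ...) {
  s <- object$surface
  out <- list(variant = object$variant, n_grid = nrow(s),
              n_reps = object$n_reps, best = coef(object),
              best_cost = s$cost[object$best],
              best_aic = s$aic[object$best],
              cost_range = range(s$cost),
              surface = s[order(s$cost), , drop = FALSE])
  class(out) <- "summary.ctl_fit"
  out
}

#' @export
print.summary.ctl_fit <- function(x, ...) {
  cat(sprintf("Grid search over %d parameter sets, %d replicates each\n",
              x$n_grid, x$n_reps))
  cat(sprintf("Best '%s': cost %.4g, AIC %.1f at\n", x$variant,
              x$best_cost, x$best_aic))
  print(x$best)
  cat("Top of the cost surface:\n")
  print(utils::head(x$surface, 5), digits = 4)
  invisible(x)
}

#' @export
plot.ctl_fit <- function(x, ...) {
  g <- x$grid
  if (ncol(g) == 2L) {
    p1 <- sort(unique(g[[1L]])); p2 <- sort(unique(g[[2L]]))
    z <- matrix(NA_real_, length(p1), length(p2))
    z[cbind(match(g[[1L]], p1), match(g[[2L]], p2))] <- x$surface$cost
    graphics::image(p1, p2, log10(z), xlab = names(g)[1L],
                    ylab = names(g)[2L],
                    main = sprintf("log10 cost surface ('%s')", x$variant),
                    col = grDevices::hcl.colors(24, "viridis", rev = TRUE),
                    ...)
    b <- coef(x)
    graphics::points(b[[names(g)[1L]]], b[[names(g)[2L]]], pch = 4,
                     cex = 2, lwd = 2)
  } else {
    graphics::plot(x$surface$cost, log = "y", xlab = "grid point",
                   ylab = "mean cost", ...)
    graphics::points(x$best, x$surface$cost[x$best], pch = 4, cex = 2)
  }
  invisible(x)
}

#' @export
simulate.ctl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sims <- lapply(seq_len(nsim), function(i)
    ctl_simulate(object$config, object$best_hypothesis,
                 motility = object$motility, duration = object$duration))
  if (nsim == 1L) sims[[1L]] else sims
}

#' Rank hypotheses by AIC
#'
#' @param results list of `cost_result` or `ctl_fit` objects.
#' @return Data frame in ascending AIC order with the hypothesis name,
#'   killing parameters, `T_death`, lowest cost and AIC, mirroring the
#'   model-comparison tables.
#' @export
rank_hypotheses <- function(results) {
  if (length(results) == 0L) stop("no results to rank", call. = FALSE)
  rows <- lapply(results, function(r) {
    if (inherits(r, "ctl_fit")) r <- r$best_result
    stopifnot(inherits(r, "cost_result"))
    h <- r$hypothesis
    data.frame(
      hypothesis = h$variant,
      zombie_contacts = h$zombie_contacts,
      killing_parameter = paste(sprintf("%s = %g", names(h$params),
                                        unlist(h$params)), collapse = ", "),
      T_death = h$T_death,
      lowest_cost = r$cost,
      aic = r$aic,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov distance between two binned distributions
#'
#' Maximum absolute difference of the cumulative bin masses. Reported
#' alongside the cost for reference; model selection uses the AIC.
#'
#' @param reference,model [binned_dist()] objects on the same breaks, or
#'   plain mass vectors of equal length.
#' @param n_ref,n_model optional effective sample sizes; when both are
#'   given an asymptotic two-sample p-value is attached.
#' @return The KS statistic, with attribute `p.value` when sample sizes
#'   were supplied.
#' @export
ks_compare <- function(reference, model, n_ref = NULL, n_model = NULL) {
  v <- function(h) if (inherits(h, "binned_dist")) h$probs else as.numeric(h)
  e <- v(reference); m <- v(model)
  if (length(e) != length(m))
    stop("distributions must share the same bins", call. = FALSE)
  D <- max(abs(cumsum(e) - cumsum(m)))
  if (!is.null(n_ref) && !is.null(n_model)) {
    ne <- n_ref * n_model / (n_ref + n_model)
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    j <- 1:100
    attr(D, "p.value") <- min(1, max(0, 2 * sum((-1)^(j - 1) *
                                                  exp(-2 * lambda^2 * j^2))))
  }
  D
}
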