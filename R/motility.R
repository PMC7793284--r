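#' Binned distribution
#'
#' A minimal histogram container used for the empirical speed, turning-angle
#' and readout distributions: strictly increasing bin edges plus one
#' probability (or normalized mass) per bin.
#'
#' @param breaks numeric vector of bin edges, strictly increasing,
#'   length `length(probs) + 1`.
#' @param probs non-negative bin probabilities summing to 1 (within 1e-9).
#' @param normalized if `FALSE`, `probs` holds unnormalized mass and the
#'   sum-to-one check is skipped.
#' @return An object of class `binned_dist`.
#' @examples
#' h <- binned_dist(c(0, 4, 6), c(0.25, 0.75))
#' sample_from_histogram(h, 5)
#' @export
binned_dist <- function(breaks, probs, normalized = TRUE) {
  if (length(breaks) != length(probs) + 1L)
    stop("need length(breaks) == length(probs) + 1", call. = FALSE)
  if (length(probs) == 0L) stop("empty histogram", call. = FALSE)
  if (any(diff(breaks) < 0)) stop("bin edges must be increasing", call. = FALSE)
  if (any(probs < 0)) stop("bin probabilities must be non-negative",
                           call. = FALSE)
  if (normalized && abs(sum(probs) - 1) > 1e-9)
    stop("bin probabilities must sum to 1 (within 1e-9)", call. = FALSE)
  structure(list(breaks = as.numeric(breaks), probs = as.numeric(probs)),
            class = "binned_dist")
}

#' @export
print.binned_dist <- function(x, ...) {
  cat(sprintf("Binned distribution: %d bins on [%g, %g], mass %.6f\n",
              length(x$probs), min(x$breaks), max(x$breaks), sum(x$probs)))
  invisible(x)
}

#' Sample from a binned distribution
#'
#' Selects a bin with its probability, then draws uniformly within the bin.
#' A zero-width bin returns its left edge.
#'
#' @param hist a [binned_dist()].
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_from_histogram <- function(hist, n = 1L) {
  stopifnot(inherits(hist, "binned_dist"))
  k <- sample.int(length(hist$probs), n, replace = TRUE, prob = hist$probs)
  a <- hist$breaks[k]
  b <- hist$breaks[k + 1L]
  a + stats::runif(n) * (b - a)
}

#' Motility model: speed and turning-angle histograms
#'
#' @param speed a [binned_dist()] of speeds (micrometres per minute).
#' @param turn a [binned_dist()] of turning angles (radians, on `[0, pi]`).
#' @return An object of class `motility_model`.
#' @seealso [default_motility_model()]
#' @export
motility_model <- function(speed, turn) {
  stopifnot(inherits(speed, "binned_dist"), inherits(turn, "binned_dist"))
  if (min(turn$breaks) < 0 || max(turn$breaks) > pi + 1e-9)
    stop("turning-angle bins must lie within [0, pi]", call. = FALSE)
  if (any(speed$breaks < 0))
    stop("speed bins must be non-negative", call. = FALSE)
  structure(list(speed = speed, turn = turn), class = "motility_model")
}

# Frozen synthetic stand-in histograms. The published speed and turning-angle
# distributions exist only as figure panels, so the package ships a
# documented synthetic pair: a right-skewed speed distribution on
# [0, 12] um/min with mean 4.5 um/min (slow antigen-engaged CTLs) and a
# forward-biased turning-angle distribution on [0, pi]. Both are versioned
# constants; replace them via motility_model() when measured histograms are
# available.
.speed_probs <- c(0.0245122649, 0.1159581548, 0.1693066984, 0.1744237253,
                  0.1515548512, 0.1189996104, 0.0873619299, 0.0611354874,
                  0.0412747118, 0.0270999665, 0.0174010513, 0.0109715482)
.turn_probs <- c(0.0571492257, 0.1289597888, 0.1578933180, 0.1583744969,
                 0.1419501678, 0.1172441280, 0.0902387502, 0.0647204937,
                 0.0427755006, 0.0252625709, 0.0122228378, 0.0032087215)

#' Default synthetic motility model
#'
#' Synthetic stand-in for measured CTL motility: speeds binned on
#' `[0, 12]` um/min with mean 4.5 um/min, and turning angles on `[0, pi]`
#' biased towards forward persistence (mean turn about 64 degrees). These are
#' versioned constants shipped with the package, intended to be replaced by
#' user-supplied measured histograms via [motility_model()].
#'
#' @return A `motility_model`.
#' @examples
#' m <- default_motility_model()
#' mean(sample_from_histogram(m$speed, 1e4))
#' @export
default_motility_model <- function() {
  motility_model(
    speed = binned_dist(seq(0, 12, 1), .speed_probs / sum(.speed_probs)),
    turn = binned_dist(seq(0, pi, length.out = 13),
                       .turn_probs / sum(.turn_probs)))
}

#' Read or write a histogram as TSV
#'
#' Three-column tab-separated layout with a header line:
#' `bin_left`, `bin_right`, `probability`. Bins must be contiguous.
#'
#' @param path file path.
#' @param hist a [binned_dist()].
#' @param normalized passed on to [binned_dist()] when reading.
#' @return `read_histogram_tsv` returns a `binned_dist`;
#'   `write_histogram_tsv` returns `path` invisibly.
#' @export
read_histogram_tsv <- function(path, normalized = TRUE) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("bin_left", "bin_right")
  if (!all(need %in% names(d)) || ncol(d) < 3L)
    stop("histogram TSV needs columns bin_left, bin_right and a value column",
         call. = FALSE)
  val <- d[[setdiff(names(d), need)[1L]]]
  if (nrow(d) > 1L && any(abs(d$bin_left[-1L] - d$bin_right[-nrow(d)]) > 1e-9))
    stop("histogram bins must be contiguous", call. = FALSE)
  binned_dist(c(d$bin_left, d$bin_right[nrow(d)]), val,
              normalized = normalized)
}

#' @rdname read_histogram_tsv
#' @export
write_histogram_tsv <- function(hist, path) {
  stopifnot(inherits(hist, "binned_dist"))
  n <- length(hist$probs)
  d <- data.frame(bin_left = hist$breaks[seq_len(n)],
                  bin_right = hist$breaks[seq_len(n) + 1L],
                  probability = hist$probs)
  utils::write.table(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rotate a direction by a turning angle in a random plane
#'
#' Returns a unit vector at the requested angle from `direction`, with the
#' rotation plane chosen uniformly over the azimuth (the rotation axis is
#' uniform on the circle of directions perpendicular to the current heading).
#'
#' @param direction unit 3-vector.
#' @param angle turning angle in radians, in `[0, pi]`.
#' @return Unit 3-vector with `sum(direction * result) == cos(angle)`.
#' @examples
#' d <- c(1, 0, 0)
#' sum(d * reorient_direction(d, pi / 3))  # 0.5
#' @export
reorient_direction <- function(direction, angle) {
  if (length(direction) != 3L || !all(is.finite(direction)))
    stop("'direction' must be a finite 3-vector", call. = FALSE)
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop("'direction' must be non-zero", call. = FALSE)
  if (abs(n - 1) > 1e-9)
    stop("'direction' must have unit norm", call. = FALSE)
  if (!is.finite(angle) || angle < 0 || angle > pi + 1e-12)
    stop("'angle' must be in [0, pi]", call. = FALSE)
  reorient_cpp(direction, angle)
}
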