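#' Local maxima with height, prominence, and distance constraints
#'
#' Peak picking in the `findpeaks` idiom: candidate local maxima are
#' filtered by minimum height and topographic prominence, then pruned so
#' that no two retained peaks are closer than `min_distance` samples
#' (higher peaks win, as in the usual greedy rule).
#'
#' @param x numeric signal.
#' @param min_height smallest admissible peak value.
#' @param min_prominence smallest admissible prominence.
#' @param min_distance smallest admissible spacing, in samples.
#' @return integer vector of peak indices, increasing.
#' @export
find_signal_peaks <- function(x, min_height = -Inf, min_prominence = 0,
                              min_distance = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  dx <- diff(x)
  idx <- which(dx[-(n - 1)] > 0 & dx[-1] <= 0) + 1L  # rising then not rising
  idx <- idx[x[idx] >= min_height]
  if (!length(idx)) return(integer(0))
  if (min_prominence > 0) {
    prom <- vapply(idx, function(i) peak_prominence(x, i), numeric(1))
    idx <- idx[prom >= min_prominence]
    if (!length(idx)) return(integer(0))
  }
  if (min_distance > 0 && length(idx) > 1) {
    ord <- idx[order(x[idx], decreasing = TRUE)]
    keep <- logical(0)
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(kept - i) >= min_distance)) {
        kept <- c(kept, i)
      }
    }
    idx <- sort(kept)
  }
  idx
}

# Topographic prominence of the peak at index i: height above the higher of
# the two key saddles (lowest point between the peak and the nearest higher
# ground on each side, or the signal end).
peak_prominence <- function(x, i) {
  n <- length(x)
  left <- if (i > 1) {
    higher <- which(x[seq_len(i - 1)] > x[i])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(x[lo:(i - 1L)])
  } else x[i]
  right <- if (i < n) {
    higher <- which(x[seq(i + 1L, n)] > x[i])
    hi <- if (length(higher)) i + min(higher) - 1L else n
    min(x[(i + 1L):hi])
  } else x[i]
  x[i] - max(left, right)
}

# Dominant stride period (samples) from the autocorrelation of a
# mean-centred oscillatory signal; searched between 0.4 and 2.5 s.
estimate_stride_samples <- function(x, fs) {
  x <- x - mean(x)
  lo <- max(2L, round(0.4 * fs))
  hi <- min(length(x) - 2L, round(2.5 * fs))
  if (hi <= lo) return(round(1.08 * fs))
  ac <- stats::acf(x, lag.max = hi, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  lag <- (lo:hi)[which.max(ac[lo:hi + 1L])]
  lag
}

# Remove the least-squares line from x (fit against sample index).
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - (sum(t * x) / sum(t * t)) * t
}

cumtrapz1 <- function(t, x) as.numeric(pracma::cumtrapz(t, x))

# Run body with a deterministic RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Keep only peaks whose amplitude is commensurate with the bulk of the
# detected peaks of the same kind (event lobes cluster tightly in
# amplitude; isolated noise bumps sit far below the cluster median).
consistent_peaks <- function(x, idx, frac = 0.4) {
  if (length(idx) < 3) return(idx)
  idx[abs(x[idx]) >= frac * stats::median(abs(x[idx]))]
}

# Derive a 32-bit-safe substream seed (double arithmetic, then reduce).
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 131 + as.numeric(stream)) %% 2147483629)
}

# Normal draws truncated at +/- 3 SD (resampling the tails).
rnorm_trunc3 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > 3 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > 3 * sd
  }
  x
}
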