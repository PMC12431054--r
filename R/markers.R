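#' Temporal gait markers per stride
#'
#' For each foot `F` and each of its strides `HS_F(i) -> HS_F(i+1)`:
#' step time is `HS_F(i)` minus the preceding contralateral heel strike;
#' stance is the first ipsilateral toe-off after `HS_F(i)` minus
#' `HS_F(i)`; swing is stride minus stance; initial double support is the
#' contralateral toe-off following `HS_F(i)` minus `HS_F(i)`; terminal
#' double support is the ipsilateral toe-off minus the contralateral heel
#' strike preceding it inside the stride; single support is the
#' contralateral swing inside the stride (contralateral toe-off to
#' contralateral heel strike). Strides missing any interleaved event, or
#' not fully inside a mask window, are dropped and counted.
#'
#' @param events_L,events_R per-foot [event_series()].
#' @param mask optional data frame of retained walking windows (`start`,
#'   `end`, seconds); a stride is kept only if fully inside one window.
#' @param max_stride_time strides longer than this are discarded (guards
#'   against strides spanning the turn when no mask is available);
#'   `Inf` disables the guard.
#' @return a `stride_table` data frame, one row per retained stride, with
#'   attribute `dropped` (number of discarded strides).
#' @export
temporal_markers <- function(events_L, events_R, mask = NULL,
                             max_stride_time = Inf) {
  one_foot <- function(own, contra) {
    hsF <- own$hs; toF <- own$to
    hsC <- contra$hs; toC <- contra$to
    rows <- list(); dropped <- 0L
    for (i in seq_len(max(0L, length(hsF) - 1L))) {
      a <- hsF[i]; b <- hsF[i + 1L]
      if (!is.null(mask) &&
          !any(mask$start - 1e-9 <= a & b <= mask$end + 1e-9)) next
      stride <- b - a
      if (stride > max_stride_time) { dropped <- dropped + 1L; next }
      to_own <- toF[toF > a & toF < b]
      to_c <- toC[toC > a & toC < b]
      hs_c <- hsC[hsC > a & hsC < b]
      hs_prev <- hsC[hsC < a]
      if (length(to_own) != 1L || length(to_c) != 1L || length(hs_c) != 1L) {
        dropped <- dropped + 1L; next
      }
      stance <- to_own - a
      # the preceding contralateral strike must belong to the same walking
      # bout: a "step" spanning the turn is not a step
      step_t <- if (length(hs_prev) && a - max(hs_prev) < stride)
        a - max(hs_prev) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        foot = own$foot, t_start = a, t_end = b,
        step_time = step_t,
        stride_time = stride, stance_time = stance,
        swing_time = stride - stance,
        single_support = hs_c - to_c,
        ds_initial = to_c - a,
        ds_terminal = to_own - hs_c,
        ds_total = (to_c - a) + (to_own - hs_c))
    }
    list(rows = rows, dropped = dropped)
  }
  l <- one_foot(events_L, events_R)
  r <- one_foot(events_R, events_L)
  out <- do.call(rbind, c(l$rows, r$rows))
  if (is.null(out))
    out <- data.frame(foot = character(0), t_start = numeric(0),
                      t_end = numeric(0), step_time = numeric(0),
                      stride_time = numeric(0), stance_time = numeric(0),
                      swing_time = numeric(0), single_support = numeric(0),
                      ds_initial = numeric(0), ds_terminal = numeric(0),
                      ds_total = numeric(0))
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("stride_table", "data.frame"),
            dropped = l$dropped + r$dropped)
}

#' Weinberg step/stride length from a foot-acceleration segment
#'
#' Returns `K * (max(aZ) - min(aZ))^(1/4)` over the segment, where `aZ`
#' is the gravity-corrected vertical acceleration
#' `ax*sin(theta) + az*cos(theta) - g`, with the pitch angle `theta`
#' integrated from the medial-lateral gyroscope over the segment and
#' linearly drift-reset.
#'
#' @param ax,az,gy foot accelerometer x/z and medial-lateral gyroscope
#'   samples over exactly one step (or one stride).
#' @param fs sampling rate, Hz.
#' @param K calibration constant (> 0), from [calibrate_K()].
#' @param g gravitational acceleration, m/s^2.
#' @return length in meters (>= 0; 0 with a warning for a flat segment).
#' @export
weinberg_length <- function(ax, az, gy, fs, K, g = 9.81) {
  if (K <= 0) stop("K must be positive")
  r <- weinberg_root(ax, az, gy, fs, g)^4
  if (r == 0) { warning("flat acceleration segment"); return(0) }
  K * r^(1 / 4)
}

# (amax - amin)^(1/4) of the projected vertical acceleration; shared by
# estimation and calibration.
weinberg_root <- function(ax, az, gy, fs, g = 9.81) {
  t <- seq_along(gy) / fs
  theta <- detrend_linear(cumtrapz1(t, gy))
  aZ <- ax * sin(theta) + az * cos(theta) - g
  (max(aZ) - min(aZ))^(1 / 4)
}

#' Calibrate the Weinberg constant against a known distance
#'
#' `K = distance / sum(roots)`, where the roots are the quartic-root
#' acceleration ranges of the calibration steps.
#'
#' @param measured_range_roots vector of `(amax - amin)^(1/4)` values, one
#'   per calibration step.
#' @param true_total_distance known distance covered by those steps, meters.
#' @return `K`.
#' @export
calibrate_K <- function(measured_range_roots, true_total_distance) {
  if (length(measured_range_roots) < 3) stop("need at least 3 calibration steps")
  if (true_total_distance <= 0) stop("distance must be positive")
  s <- sum(measured_range_roots)
  if (s <= 0) stop("degenerate calibration: zero acceleration ranges")
  true_total_distance / s
}

#' Inverted-pendulum step length
#'
#' `2 * sqrt(2*l*h - h^2)` for vertical excursion `h` and pendulum length
#' `l`; stride length is the sum of the right and left step lengths.
#'
#' @param h vertical excursion of the centre of mass, meters.
#' @param l pendulum length, meters.
#' @return step length, meters.
#' @export
pendulum_step_length <- function(h, l) {
  if (any(h < 0)) stop("h must be non-negative")
  if (any(h >= 2 * l)) stop("h >= 2l: pendulum relation has an imaginary root")
  2 * sqrt(2 * l * h - h^2)
}

#' Macro and spatiotemporal summary of a stride table
#'
#' Cadence is `2 * strides / sum(stride times) * 60` steps/min; average
#' velocity is `sum(stride lengths) / sum(stride times)` (reported in
#' cm/s), computed over retained strides only, walkway-style; stride
#' velocity is per-stride length over time. The summary reports mean and
#' SD per marker over retained strides (macro markers have one value per
#' trial, reported with SD 0).
#'
#' @param strides a `stride_table`, optionally with `step_length` and
#'   `stride_length` columns in meters.
#' @param task trial label stored in the result.
#' @return a `trial_summary` data frame (`marker`, `units`, `mean`, `sd`,
#'   `n`).
#' @export
trial_summary <- function(strides, task = "single_task") {
  if (!nrow(strides)) stop("no retained strides")
  num <- function(v) v[!is.na(v)]
  row <- function(marker, units, vals) {
    vals <- num(vals)
    if (!length(vals)) return(NULL)
    data.frame(marker = marker, units = units, mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               n = length(vals))
  }
  cadence <- 2 * nrow(strides) / sum(strides$stride_time) * 60
  out <- list(row("cadence", "steps/min", cadence),
              row("step_time", "s", strides$step_time),
              row("stride_time", "s", strides$stride_time),
              row("stance_time", "s", strides$stance_time),
              row("swing_time", "s", strides$swing_time),
              row("single_support", "s", strides$single_support),
              row("double_support", "s", strides$ds_total))
  if (!is.null(strides$stride_length)) {
    ok <- !is.na(strides$stride_length)
    if (any(ok)) {
      vel <- sum(strides$stride_length[ok]) / sum(strides$stride_time[ok]) * 100
      out <- c(list(row("velocity", "cm/s", vel)), out,
               list(row("stride_length", "cm", strides$stride_length * 100),
                    row("stride_velocity", "cm/s",
                        strides$stride_length[ok] /
                          strides$stride_time[ok] * 100)))
    }
  }
  if (!is.null(strides$step_length))
    out <- c(out, list(row("step_length", "cm", strides$step_length * 100)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("trial_summary", "data.frame"), task = task,
            n_strides = nrow(strides))
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("Trial summary [%s], %d retained strides:\n",
              attr(x, "task"), attr(x, "n_strides")))
  print.data.frame(cbind(x[, c("marker", "units")],
                         `mean+/-sd` = sprintf("%.3f +/- %.3f", x$mean, x$sd),
                         n = x$n), row.names = FALSE)
  invisible(x)
}
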