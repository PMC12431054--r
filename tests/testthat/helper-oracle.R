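# Independent fixtures and oracles shared across tests.

# Construct a random but structurally valid bilateral HS/TO train directly
# (independently of the package's generator): per stride, draw duration,
# stance fraction and double-support fraction, and lay events out in the
# canonical cycle HS_A, TO_B, HS_B, TO_A.
random_event_train <- function(n_strides = 8, seed = 1, fs = 128) {
  set.seed(seed)
  first <- sample(c("left", "right"), 1)
  other <- setdiff(c("left", "right"), first)
  t <- runif(1, 0.5, 2)
  rows <- list()
  for (i in seq_len(n_strides)) {
    Ti <- runif(1, 0.8, 1.5)
    sf <- runif(1, 0.55, 0.72)
    dsf <- runif(1, 0.05, 2 * sf - 1)  # keeps TO_B after HS_A and order valid
    rows[[length(rows) + 1L]] <- data.frame(
      time = t + c(0, dsf / 2 * Ti, Ti / 2, sf * Ti),
      foot = c(first, other, other, first),
      kind = c("HS", "TO", "HS", "TO"))
    t <- t + Ti
  }
  rows[[length(rows) + 1L]] <- data.frame(time = t, foot = first, kind = "HS")
  ev <- do.call(rbind, rows)
  # snap to the sample grid, as detections would be
  ev$time <- round(ev$time * fs) / fs
  ev[order(ev$time), ]
}

# Brute-force interval calculator: walks the merged, time-sorted event list
# and derives every temporal marker for each complete same-foot stride by
# direct subsetting, with no masking/repair logic.
oracle_markers <- function(ev) {
  out <- list()
  for (f in c("left", "right")) {
    g <- setdiff(c("left", "right"), f)
    hsF <- ev$time[ev$foot == f & ev$kind == "HS"]
    for (i in seq_len(max(0, length(hsF) - 1))) {
      a <- hsF[i]; b <- hsF[i + 1]
      inwin <- function(foot, kind)
        ev$time[ev$foot == foot & ev$kind == kind & ev$time > a & ev$time < b]
      toF <- inwin(f, "TO"); toG <- inwin(g, "TO"); hsG <- inwin(g, "HS")
      if (length(toF) != 1 || length(toG) != 1 || length(hsG) != 1) next
      prev <- ev$time[ev$foot == g & ev$kind == "HS" & ev$time < a]
      out[[length(out) + 1L]] <- data.frame(
        foot = f, t_start = a,
        step_time = if (length(prev) && a - max(prev) < b - a)
          a - max(prev) else NA_real_,
        stride_time = b - a, stance_time = toF - a,
        swing_time = (b - a) - (toF - a),
        single_support = hsG - toG, ds_initial = toG - a,
        ds_terminal = toF - hsG, ds_total = (toG - a) + (toF - hsG))
    }
  }
  d <- do.call(rbind, out)
  d[order(d$t_start), ]
}

events_from_train <- function(ev, foot) {
  event_series(foot, ev$time[ev$foot == foot & ev$kind == "HS"],
               ev$time[ev$foot == foot & ev$kind == "TO"],
               modality = "reference")
}

zero_var_profile <- function(...) {
  gait_profile(stride_time_sd = 0, step_length_sd = 0, ...)
}
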