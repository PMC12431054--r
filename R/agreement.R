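#' Paired sample of one gait marker from two systems
#'
#' @param marker marker name.
#' @param ref_values,test_values aligned per-subject (or per-trial) values;
#'   `ref_values` come from the reference system.
#' @param units unit label.
#' @return an object of class `paired_marker_sample`.
#' @export
paired_marker_sample <- function(marker, ref_values, test_values, units = "") {
  if (length(ref_values) != length(test_values))
    stop("ref and test values must be aligned")
  if (length(ref_values) < 2) stop("need at least 2 pairs")
  structure(list(marker = marker, units = units,
                 ref = as.numeric(ref_values), test = as.numeric(test_values)),
            class = "paired_marker_sample")
}

#' Mean absolute error between paired measurements
#'
#' @param sample a [paired_marker_sample()].
#' @return list with `mean` and `sd` (sample SD) of the per-pair absolute
#'   differences.
#' @export
mae_stats <- function(sample) {
  d <- abs(sample$test - sample$ref)
  list(mean = mean(d), sd = stats::sd(d))
}

#' Mean absolute error percentage
#'
#' Mean of `100 * |test - ref| / |ref|` over pairs.
#'
#' @param sample a [paired_marker_sample()].
#' @return MAEP in percent.
#' @export
maep <- function(sample) {
  if (any(sample$ref == 0)) stop("MAEP undefined: reference value of zero")
  mean(100 * abs(sample$test - sample$ref) / abs(sample$ref))
}

#' Pearson correlation between the two systems
#'
#' @param sample a [paired_marker_sample()].
#' @return list with `r` and the two-sided `p` from the t transform with
#'   n-2 degrees of freedom.
#' @export
pearson_agreement <- function(sample) {
  if (length(sample$ref) < 3) stop("need at least 3 pairs for a correlation")
  if (stats::sd(sample$ref) == 0 || stats::sd(sample$test) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(sample$test, sample$ref, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman method-agreement analysis
#'
#' Differences are `test - ref`; the bias is their mean and the 95% limits
#' of agreement are `bias +/- 1.96 * SD(differences)`.
#'
#' @param sample a [paired_marker_sample()].
#' @return an object of class `bland_altman` with `bias`, `loa_low`,
#'   `loa_high`, per-point `means` and `diffs`, and the marker metadata.
#' @export
bland_altman <- function(sample) {
  d <- sample$test - sample$ref
  m <- (sample$test + sample$ref) / 2
  s <- stats::sd(d)
  structure(list(marker = sample$marker, units = sample$units,
                 bias = mean(d), loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s, means = m, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman [%s]: bias %.4g %s, 95%% LoA [%.4g, %.4g]\n",
              x$marker, x$bias, x$units, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, pch = 19, col = "grey30",
                 xlab = sprintf("Mean of methods (%s)", x$units),
                 ylab = sprintf("Difference, test - ref (%s)", x$units),
                 main = sprintf("Bland-Altman: %s", x$marker), ...)
  graphics::abline(h = x$bias, col = "red", lty = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "darkgreen", lty = 2)
  invisible(x)
}

#' Full agreement statistics for one marker and modality
#'
#' @param sample a [paired_marker_sample()].
#' @return one-row data frame: MAE mean/SD, MAEP, `r`, `p`, bias, limits
#'   of agreement. Correlation fields are `NA` (with a flag) when the
#'   sample has no variance.
#' @export
agreement_result <- function(sample) {
  m <- mae_stats(sample)
  mp <- tryCatch(maep(sample), error = function(e) NA_real_)
  pe <- tryCatch(pearson_agreement(sample),
                 error = function(e) list(r = NA_real_, p = NA_real_))
  ba <- bland_altman(sample)
  data.frame(marker = sample$marker, units = sample$units,
             ref_mean = mean(sample$ref), ref_sd = stats::sd(sample$ref),
             test_mean = mean(sample$test), test_sd = stats::sd(sample$test),
             mae_mean = m$mean, mae_sd = m$sd, maep = mp,
             r = pe$r, p_value = pe$p,
             bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
             n = length(sample$ref))
}

#' Agreement report across markers and modalities
#'
#' Builds the two report tables (per-marker means and MAE per modality;
#' per-marker correlation and p per modality), writes them as CSV when a
#' directory is given, and optionally renders Bland-Altman plots per
#' marker-modality pair plus an r-versus-MAEP scatter with threshold
#' guides at r = 0.6 and MAEP = 10%.
#'
#' @param samples named list (by modality) of lists of
#'   [paired_marker_sample()] objects.
#' @param task trial label.
#' @param out_dir optional output directory for CSVs and plots.
#' @param plots logical; render plot files (requires `out_dir`).
#' @return an `agreement_report`: list with `task`, `results` (long data
#'   frame with a `modality` column), and file paths if written.
#' @export
agreement_report <- function(samples, task = "single_task", out_dir = NULL,
                             plots = FALSE) {
  results <- do.call(rbind, lapply(names(samples), function(mod) {
    rows <- do.call(rbind, lapply(samples[[mod]], agreement_result))
    if (is.null(rows)) return(NULL)
    cbind(modality = mod, rows)
  }))
  rownames(results) <- NULL
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, sprintf("markers_mae_%s.csv", task))
    utils::write.csv(results[, c("modality", "marker", "units", "ref_mean",
                                 "ref_sd", "test_mean", "test_sd",
                                 "mae_mean", "mae_sd", "maep", "n")],
                     f1, row.names = FALSE)
    f2 <- file.path(out_dir, sprintf("markers_correlation_%s.csv", task))
    utils::write.csv(results[, c("modality", "marker", "r", "p_value", "n")],
                     f2, row.names = FALSE)
    files <- c(files, f1, f2)
    if (plots) {
      for (mod in names(samples)) for (s in samples[[mod]]) {
        fp <- file.path(out_dir, sprintf("bland_altman_%s_%s_%s",
                                         task, mod, s$marker))
        files <- c(files, plot_to_file(fp, function() plot(bland_altman(s))))
      }
      fp <- file.path(out_dir, sprintf("r_vs_maep_%s", task))
      files <- c(files, plot_to_file(fp, function()
        plot_r_vs_maep(results)))
    }
  }
  structure(list(task = task, results = results, files = files),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report [%s]\n", x$task))
  d <- x$results
  print.data.frame(data.frame(modality = d$modality, marker = d$marker,
                              mae = sprintf("%.3f +/- %.3f", d$mae_mean, d$mae_sd),
                              maep = sprintf("%.1f%%", d$maep),
                              r = round(d$r, 3)), row.names = FALSE)
  invisible(x)
}

#' Correlation versus error-percentage scatter
#'
#' @param results the `results` table of an [agreement_report()].
#' @param r_threshold,maep_threshold guide lines.
#' @export
plot_r_vs_maep <- function(results, r_threshold = 0.6, maep_threshold = 10) {
  d <- results[!is.na(results$r) & !is.na(results$maep), ]
  mods <- unique(d$modality)
  cols <- stats::setNames(seq_along(mods) + 1L, mods)
  graphics::plot(d$maep, d$r, col = cols[d$modality], pch = 19,
                 xlab = "MAEP (%)", ylab = "Pearson r",
                 main = "Correlation vs mean absolute error percentage",
                 ylim = c(min(0, min(d$r)), 1))
  graphics::abline(h = r_threshold, v = maep_threshold, lty = 2, col = "grey50")
  graphics::legend("bottomright", legend = mods, col = cols, pch = 19, bty = "n")
  invisible(d)
}

# Render a plot closure to SVG (falling back to PDF where no SVG device
# is available); returns the path written.
plot_to_file <- function(path_base, draw) {
  ok <- tryCatch({
    grDevices::svg(paste0(path_base, ".svg"), width = 5, height = 4)
    draw(); grDevices::dev.off(); TRUE
  }, error = function(e) FALSE)
  if (ok) return(paste0(path_base, ".svg"))
  grDevices::pdf(paste0(path_base, ".pdf"), width = 5, height = 4)
  draw(); grDevices::dev.off()
  paste0(path_base, ".pdf")
}
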