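#' Clustered trough-train parameters
#'
#' Spontaneous activity in the neonatal cortex arrives in clusters (spindle
#' bursts): a slow trough initiates each cluster and fast (gamma-range) troughs
#' follow within it. The generator models this as a renewal cluster process:
#' cluster sizes are `1 + Poisson(events_per_cluster_mean - 1)`, intra-cluster
#' (fast) intervals are log-normal `LN(mu_intra, sigma_intra)`, and the gap from
#' the last event of one cluster to the first of the next is log-normal
#' `LN(mu_gap, sigma_gap)`.
#'
#' `train_params()` solves `mu_gap` and `mu_intra` from the two published
#' summary statistics that the train must reproduce: the mean event rate and
#' the median instantaneous frequency (median of reciprocal consecutive
#' inter-event intervals). With expected fraction `f_gap = 1/m` of all
#' intervals being gaps (`m` = mean cluster size) and intra-cluster intervals
#' lying below the median, the pooled median interval is the
#' `alpha = 1 - m/2` quantile of the gap distribution; `mu_gap` places that
#' quantile at `1/median_freq_hz`, and `mu_intra` is then fixed by the mean
#' rate. For `events_per_cluster_mean = 1` (unclustered discharges, as in the
#' pharmacologically induced slice regimes) the gap distribution carries the
#' mean rate alone.
#'
#' @param mean_rate_per_min target mean event rate, events/min.
#' @param median_freq_hz target median instantaneous frequency, Hz. Ignored
#'   when `events_per_cluster_mean == 1`.
#' @param events_per_cluster_mean mean cluster size `m`; must be in `[1, 2)`
#'   (the pooled-median construction requires gaps to be the majority interval
#'   class at the median).
#' @param sigma_intra,sigma_gap log-scale standard deviations of the interval
#'   distributions.
#' @param refractory_s minimum realized interval, seconds.
#' @return a `bq_train_params` list with the solved `mu_intra`, `mu_gap` and
#'   the implied mean intra-cluster and gap intervals.
#' @examples
#' train_params(63, 0.82)
#' @export
train_params <- function(mean_rate_per_min,
                         median_freq_hz = NULL,
                         events_per_cluster_mean = 1.9,
                         sigma_intra = 0.35,
                         sigma_gap = 0.05,
                         refractory_s = 0.012) {
  check_number(mean_rate_per_min, "mean_rate_per_min", lower = 0)
  check_number(events_per_cluster_mean, "events_per_cluster_mean", lower = 1)
  check_number(sigma_intra, "sigma_intra", lower = 0, strict_lower = TRUE)
  check_number(sigma_gap, "sigma_gap", lower = 0, strict_lower = TRUE)
  check_number(refractory_s, "refractory_s", lower = 0, strict_lower = TRUE)
  m <- events_per_cluster_mean
  if (m >= 2) {
    rlang::abort("`events_per_cluster_mean` must be < 2: the pooled median is placed in the gap distribution, which requires gaps to make up more than half of all intervals.")
  }
  out <- list(
    mean_rate_per_min = mean_rate_per_min,
    median_freq_hz = median_freq_hz,
    events_per_cluster_mean = m,
    sigma_intra = sigma_intra,
    sigma_gap = sigma_gap,
    refractory_s = refractory_s,
    mu_intra = NA_real_, mu_gap = NA_real_,
    mean_intra_s = NA_real_, mean_gap_s = NA_real_
  )
  class(out) <- "bq_train_params"
  if (mean_rate_per_min == 0) return(out)

  lambda <- mean_rate_per_min / 60        # events per second
  mean_interval <- 1 / lambda             # pooled mean interval

  if (m == 1) {
    # Pure renewal: the gap distribution carries the mean rate.
    out$mu_gap <- log(mean_interval) - sigma_gap^2 / 2
    out$mean_gap_s <- mean_interval
    out$median_freq_hz <- median_freq_hz %||% (1 / exp(out$mu_gap))
    return(out)
  }

  if (is.null(median_freq_hz)) {
    rlang::abort("`median_freq_hz` is required when `events_per_cluster_mean` > 1.")
  }
  check_number(median_freq_hz, "median_freq_hz", lower = 0, strict_lower = TRUE)
  med_interval <- 1 / median_freq_hz
  f_gap <- 1 / m
  alpha <- 1 - m / 2                      # gap-quantile level of the pooled median
  out$mu_gap <- log(med_interval) - sigma_gap * stats::qnorm(alpha)
  out$mean_gap_s <- exp(out$mu_gap + sigma_gap^2 / 2)

  mean_intra <- (mean_interval - f_gap * out$mean_gap_s) / (1 - f_gap)
  if (!is.finite(mean_intra) || mean_intra <= refractory_s) {
    rlang::abort(paste0(
      "Infeasible train parameters: with the requested mean rate and median ",
      "frequency the implied mean intra-cluster interval is ",
      sprintf("%.4f s", mean_intra), ", not above the refractory period. ",
      "Lower `sigma_gap` or adjust `events_per_cluster_mean`."
    ))
  }
  out$mean_intra_s <- mean_intra
  out$mu_intra <- log(mean_intra) - sigma_intra^2 / 2
  out
}

#' @export
print.bq_train_params <- function(x, ...) {
  cat("<bq_train_params>\n")
  cat(sprintf("  mean rate: %.2f events/min; median instantaneous freq: %s Hz\n",
              x$mean_rate_per_min,
              if (is.null(x$median_freq_hz)) "-" else sprintf("%.3f", x$median_freq_hz)))
  cat(sprintf("  mean cluster size: %.2f; intra LN(%.3f, %.2f); gap LN(%.3f, %.3f)\n",
              x$events_per_cluster_mean, x$mu_intra, x$sigma_intra,
              x$mu_gap, x$sigma_gap))
  cat(sprintf("  mean intra interval: %s s; mean gap: %s s; refractory: %.3f s\n",
              if (is.na(x$mean_intra_s)) "-" else sprintf("%.3f", x$mean_intra_s),
              if (is.na(x$mean_gap_s)) "-" else sprintf("%.3f", x$mean_gap_s),
              x$refractory_s))
  invisible(x)
}
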