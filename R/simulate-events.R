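#' Simulate a clustered trough train
#'
#' Draws an event train from the renewal cluster process described in
#' [train_params()]: cluster sizes `1 + Poisson(m - 1)`, log-normal
#' intra-cluster intervals, log-normal inter-cluster gaps, all intervals
#' floored at the refractory period. The first cluster onset is placed
#' uniformly within one mean cycle so the process is approximately stationary
#' from `t = 0`.
#'
#' Each event is annotated with its cluster index and a `kind` column:
#' `"slow"` for the cluster-initial trough, `"fast"` for the within-cluster
#' troughs that follow (rendered with distinct widths by [render_lfp()]).
#'
#' @param params a `bq_train_params` object.
#' @param duration_s recording length in seconds (> 0).
#' @param seed integer seed; the train is reproduced bit-for-bit from
#'   `(params, duration_s, seed)`.
#' @return a `bq_events` tibble with columns `time_s`, `kind`, `cluster`.
#' @examples
#' tr <- make_event_train(train_params(120, 1.2), duration_s = 60, seed = 1)
#' nrow(tr) * 60 / 60  # realized events/min
#' @export
make_event_train <- function(params, duration_s, seed) {
  if (!inherits(params, "bq_train_params")) {
    rlang::abort("`params` must be created with train_params().")
  }
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (params$mean_rate_per_min == 0) {
    return(event_train(numeric(0), duration_s, kind = character(0),
                       recording_id = character(0)))
  }
  m <- params$events_per_cluster_mean
  mean_cycle <- (m - 1) * (params$mean_intra_s %||% 0) + params$mean_gap_s
  if (is.na(mean_cycle)) mean_cycle <- params$mean_gap_s

  with_stream(seed, "make_event_train", {
    n_clusters <- max(16L, ceiling(duration_s / mean_cycle * 1.4) + 16L)
    times <- kind <- cluster <- NULL
    repeat {
      k <- if (m > 1) 1L + stats::rpois(n_clusters, m - 1) else rep(1L, n_clusters)
      n_ev <- sum(k)
      cluster_id <- rep.int(seq_len(n_clusters), k)
      within <- sequence(k)
      is_first <- within == 1L
      intervals <- numeric(n_ev)
      n_intra <- sum(!is_first)
      if (n_intra > 0) {
        intervals[!is_first] <- stats::rlnorm(n_intra, params$mu_intra,
                                              params$sigma_intra)
      }
      n_gap <- sum(is_first)
      gaps <- stats::rlnorm(n_gap, params$mu_gap, params$sigma_gap)
      intervals[is_first] <- gaps
      # stationary-ish start: first cluster onset uniform within one mean cycle
      intervals[1] <- stats::runif(1, 0, mean_cycle)
      intervals <- pmax(intervals, params$refractory_s)
      intervals[1] <- min(intervals[1], mean_cycle)
      t_ev <- cumsum(intervals)
      if (t_ev[n_ev] >= duration_s) {
        keep <- t_ev < duration_s
        times <- t_ev[keep]
        kind <- ifelse(is_first[keep], "slow", "fast")
        cluster <- cluster_id[keep]
        break
      }
      n_clusters <- n_clusters * 2L  # undershot the duration; redraw larger
    }
    out <- event_train(times, duration_s, kind = kind)
    out$cluster <- cluster
    out
  })
}
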