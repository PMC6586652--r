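#' Hierarchical drift-dive detection on a summarized-dive table
#'
#' Runs the full detection chain for one animal: recover selection orders
#' (RBSA), keep candidate groups and locate the drifting segment, apply
#' the sequential threshold criteria, and (optionally) fit the buoyancy
#' trajectory filter, accepting dives with `P(z_k = 1) > 0.95`.  The
#' trajectory filter must be fitted per individual; pass one animal's
#' dives at a time.
#'
#' @param summaries summarized-dive `data.frame` for a single animal;
#'   `start_datetime` must be populated when `fit_filter = TRUE`.
#' @param segment_rules,threshold_rules rule tables (defaults: bundled
#'   files).
#' @param fit_filter fit the trajectory filter (default `TRUE`).
#' @param model a [buoyancy_model()].
#' @param seed seed passed to the MCMC.
#' @param threshold posterior acceptance threshold on `P(z_k = 1)`.
#' @param ... further arguments to [fit_trajectory_filter()] (chains,
#'   iterations, ...).
#' @return list with `candidates` (grouping stage output),
#'   `threshold` (`accepted` + `traces`), `trajectory` (fitted
#'   `drift_trajectory` or `NULL`), and `final`: a data.frame of retained
#'   dives with `dive_id`, `start_datetime`, `date`, `drift_rate` (the
#'   observed rate) and `p_in` (1 when the filter is skipped).
#' @export
detect_drift_dives <- function(summaries,
                               segment_rules = load_segment_rules(),
                               threshold_rules = read_threshold_rules(),
                               fit_filter = TRUE,
                               model = buoyancy_model(), seed = 1L,
                               threshold = 0.95, ...) {
  cand <- build_candidates(summaries, rules = segment_rules)
  thr <- apply_threshold_rules(cand$candidates, threshold_rules)
  acc <- thr$accepted
  traj <- NULL
  if (fit_filter && nrow(acc) > 0L) {
    if (any(is.na(acc$start_datetime)))
      stop("start_datetime must be populated to fit the trajectory filter")
    acc <- acc[order(acc$start_datetime), , drop = FALSE]
    tdays <- as.numeric(difftime(acc$start_datetime,
                                 acc$start_datetime[1L], units = "days"))
    # dives sharing a timestamp cannot be ordered; nudge by a second
    while (any(diff(tdays) <= 0))
      tdays <- cumsum(c(tdays[1L], pmax(diff(tdays), 1 / 86400)))
    traj <- fit_trajectory_filter(tdays, acc$drift_rate, model = model,
                                  seed = seed, ...)
    keep <- traj$observations$p_in > threshold
    final <- data.frame(dive_id = acc$dive_id,
                        start_datetime = acc$start_datetime,
                        date = as.Date(acc$start_datetime),
                        drift_rate = acc$drift_rate,
                        p_in = traj$observations$p_in,
                        stringsAsFactors = FALSE)[keep, , drop = FALSE]
  } else {
    final <- data.frame(dive_id = acc$dive_id,
                        start_datetime = acc$start_datetime,
                        date = as.Date(acc$start_datetime),
                        drift_rate = acc$drift_rate,
                        p_in = rep(1, nrow(acc)),
                        stringsAsFactors = FALSE)
  }
  list(candidates = cand, threshold = thr, trajectory = traj, final = final)
}
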