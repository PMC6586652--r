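#' Per-dive "true" drift rate from a high-resolution profile
#'
#' Computes the rate of change of depth at every time step inside the
#' drifting segment and returns the median, which is robust to occasional
#' spikes.  Sign convention as in [compute_drift_rate()]: sinking is
#' negative.
#'
#' @param profile an [high_res_profile()].
#' @param segment integer length-2: first and last sample index of the
#'   drifting segment (inclusive), containing at least 2 samples.
#' @return median per-step drift rate (m/s).
#' @export
true_drift_rate <- function(profile, segment) {
  i <- segment[1L]:segment[2L]
  if (length(i) < 2L)
    stop("drifting segment needs at least 2 samples (dive ",
         profile$dive_id, ")")
  rates <- -diff(profile$depths[i]) / diff(profile$times[i])
  stats::median(rates)
}

#' Daily averaged drift rate
#'
#' @param dates `Date` (or date-coercible) vector, one per dive.
#' @param rates drift rates (m/s), same length.
#' @return data.frame with `date`, the arithmetic mean `rate` over the
#'   dives of that UTC calendar day, and `n_dives`; days sorted.
#' @export
daily_average <- function(dates, rates) {
  dates <- as.Date(dates)
  agg <- stats::aggregate(list(rate = rates), by = list(date = dates), mean)
  cnt <- stats::aggregate(list(n_dives = rates), by = list(date = dates),
                          length)
  out <- merge(agg, cnt, by = "date")
  out[order(out$date), ]
}

#' Bias and daily-error metrics against high-resolution truth
#'
#' Implements the evaluation used to validate the detection pipeline:
#'
#' * per-dive bias — the summarized-profile drift rate minus the median
#'   "true" rate of the same dive;
#' * ODDR — observed daily averaged drift rate from the high-resolution
#'   drift dives; SDDR — daily averaged drift rate from the summarized
#'   profiles, before (`pre`) and after (`post`) the trajectory filter;
#' * msr — the mean of the squared per-day error between each SDDR and the
#'   ODDR, plus the upper 95% quantile of the squared errors.
#'
#' Days present in only one series are dropped from the error summaries
#' (pairwise-complete) and reported in `n_days_dropped`.
#'
#' @param truth data.frame of high-resolution truth with columns
#'   `dive_id`, `date`, `rate`.
#' @param post data.frame of detections after the trajectory filter, same
#'   columns.
#' @param pre optional data.frame of pre-filter candidates, same columns.
#' @return list with `bias` (per matched dive), `median_bias`, `daily`
#'   (merged ODDR/SDDR table), `msr` (named numeric: `pre`, `post`) and
#'   `se_q95` (upper 95% quantile of squared errors, same names).
#' @export
compute_validation_metrics <- function(truth, post, pre = NULL) {
  for (df in list(truth, post))
    if (!all(c("dive_id", "date", "rate") %in% names(df)))
      stop("truth/detection tables need dive_id, date, rate columns")
  m <- merge(truth[, c("dive_id", "rate")], post[, c("dive_id", "rate")],
             by = "dive_id", suffixes = c("_true", "_est"))
  bias <- data.frame(dive_id = m$dive_id,
                     bias = m$rate_est - m$rate_true)
  oddr <- daily_average(truth$date, truth$rate)
  names(oddr)[2L] <- "ODDR"
  sddr_post <- daily_average(post$date, post$rate)
  names(sddr_post)[2L] <- "SDDR_post"
  daily <- merge(oddr[, c("date", "ODDR")],
                 sddr_post[, c("date", "SDDR_post")], all = TRUE)
  if (!is.null(pre)) {
    sddr_pre <- daily_average(pre$date, pre$rate)
    names(sddr_pre)[2L] <- "SDDR_pre"
    daily <- merge(daily, sddr_pre[, c("date", "SDDR_pre")], all = TRUE)
  }
  msr_of <- function(col) {
    ok <- stats::complete.cases(daily[, c("ODDR", col)])
    se <- (daily[[col]][ok] - daily$ODDR[ok])^2
    c(msr = mean(se),
      q95 = if (length(se)) unname(stats::quantile(se, 0.95)) else NA_real_,
      n = sum(ok))
  }
  post_stats <- msr_of("SDDR_post")
  pre_stats <- if (!is.null(pre)) msr_of("SDDR_pre") else
    c(msr = NA_real_, q95 = NA_real_, n = NA_real_)
  if (post_stats[["n"]] == 0)
    warning("no overlapping days between ODDR and SDDR")
  list(bias = bias,
       median_bias = stats::median(bias$bias),
       daily = daily,
       msr = c(pre = unname(pre_stats[["msr"]]),
               post = unname(post_stats[["msr"]])),
       se_q95 = c(pre = unname(pre_stats[["q95"]]),
                  post = unname(post_stats[["q95"]])),
       n_days = c(pre = unname(pre_stats[["n"]]),
                  post = unname(post_stats[["n"]])))
}
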