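#' The eight candidate drift-dive groups
#'
#' Selection-order labels whose dives are considered candidate drift dives.
#' Of the 24 possible orders, these eight jointly contain the large
#' majority of true drift dives in high-resolution reference data; all
#' other orders are rejected outright.
#'
#' @return character vector of 8 dotted order labels.
#' @export
drift_groups <- function() {
  c("2.1.3.4", "2.1.4.3", "2.4.1.3", "3.1.2.4",
    "3.1.4.2", "3.2.1.4", "3.4.1.2", "4.2.1.3")
}

#' Assign a dive to a candidate drift group
#'
#' @param label dotted selection-order label(s), e.g. `"2.1.3.4"`.
#' @param whitelist set of accepted labels, defaults to [drift_groups()].
#' @return character vector: the label where accepted, `NA` where rejected.
#' @export
assign_group <- function(label, whitelist = drift_groups()) {
  all24 <- apply(.permutations4(), 1L, paste, collapse = ".")
  bad <- !is.na(label) & !label %in% all24
  if (any(bad))
    stop("not a valid selection-order label: ",
         paste(unique(label[bad]), collapse = ", "))
  ifelse(label %in% whitelist, label, NA_character_)
}

.permutations4 <- function() {
  g <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  g <- g[apply(g, 1L, function(r) length(unique(r)) == 4L), ]
  as.matrix(g)
}

#' Dive-shape variables of a summarized dive
#'
#' Computes the proportional shape variables used by the per-group drift
#' segment rules and threshold criteria.  Proportional values scale the
#' variables so that shorter/longer or shallower/deeper dives are
#' comparable.  With inflection points `IFP_i = (T_i, D_i)`, dive duration
#' `E` and maximum depth `M = max(D_i)`:
#'
#' * `d1..d4`: depth ratios `D_i / M`;
#' * `t1..t4`: time ratios `T_i / E`;
#' * `ps0`: descent proportion `T1 / E`; `ps1..ps3`: proportions of the
#'   dive spent on segments 1-3 (`(T_{i+1} - T_i)/E`); `ps4`:
#'   `(E - T4)/E`;
#' * `f, s, t`: depth change per unit time (m/s, positive = deepening) on
#'   segments 1-3;
#' * `sratio`: descent rate `D1/T1` divided by `f`;
#' * `meand`, `sdd`: mean and (sample) standard deviation of `d1..d4`;
#' * `r1..r4`: residuals (m) of the least-squares line through
#'   `(T_i, D_i)`;
#' * `mrratio`: smallest broken-stick residual divided by `M`;
#' * `mdepthbias`: time at maximum depth minus `E/2` (s);
#' * `mdepthr`: `mean(D_1..D_4) / M`;
#' * `avratio`: mean per-segment vertical rate after the deepest
#'   inflection point divided by the mean rate before it (auxiliary
#'   criterion; negative for a typical down-then-up dive);
#' * `hp2`, `hp3`: proportional depths of IFP2 and IFP3 (equal to `d2`,
#'   `d3`; auxiliary criteria kept under their own names).
#'
#' @param summary one row of a summarized-dive table; broken-stick
#'   residuals (`res1..res4`) must be present for `mrratio` (use
#'   [add_orders()] to recover them).
#' @param order optional `ifp_order` for the dive; recomputed when absent.
#' @return one-row `data.frame` of shape variables plus a logical
#'   `degenerate` flag (set when a zero-duration segment or zero maximum
#'   depth makes the variables undefined).
#' @export
compute_shape_variables <- function(summary, order = NULL) {
  s <- as.list(summary[1L, ])
  Ts <- c(s$T1, s$T2, s$T3, s$T4)
  Ds <- c(s$D1, s$D2, s$D3, s$D4)
  E <- s$E
  M <- max(Ds)
  if (is.null(order)) order <- recover_order(summary)
  res <- as.numeric(summary[1L, paste0("res", 1:4)])
  if (all(is.na(res))) res <- order$residuals
  seg_dt <- diff(c(0, Ts, E))
  degenerate <- M <= 0 || any(seg_dt <= 0)
  if (degenerate) M <- max(M, 1e-12)
  d <- Ds / M
  tfr <- Ts / E
  ps <- seg_dt / E
  rate <- diff(Ds) / diff(Ts)                       # f, s, t
  desc_rate <- Ds[1L] / Ts[1L]
  # least-squares line through the four inflection points
  fit <- stats::lm.fit(cbind(1, Ts), Ds)
  rres <- as.numeric(fit$residuals)
  i_deep <- order$order[1L]                         # deepest ifp (tie: earliest)
  all_t <- c(0, Ts, E)
  all_d <- c(0, Ds, 0)
  seg_rates <- diff(all_d) / diff(all_t)            # segments 0..4
  before <- seg_rates[seq_len(i_deep)]
  after <- seg_rates[(i_deep + 1L):5L]
  avr <- mean(after) / mean(before)
  out <- data.frame(
    d1 = d[1L], d2 = d[2L], d3 = d[3L], d4 = d[4L],
    t1 = tfr[1L], t2 = tfr[2L], t3 = tfr[3L], t4 = tfr[4L],
    ps0 = ps[1L], ps1 = ps[2L], ps2 = ps[3L], ps3 = ps[4L], ps4 = ps[5L],
    f = rate[1L], s = rate[2L], t = rate[3L],
    sratio = desc_rate / rate[1L],
    meand = mean(d), sdd = stats::sd(d),
    r1 = rres[1L], r2 = rres[2L], r3 = rres[3L], r4 = rres[4L],
    mrratio = min(res) / M,
    mdepthbias = Ts[i_deep] - E / 2,
    mdepthr = mean(Ds) / M,
    avratio = avr,
    hp2 = d[2L], hp3 = d[3L],
    degenerate = degenerate)
  out
}

#' Signed drift rate over a summary segment
#'
#' The drift rate is the depth change over the segment divided by the time
#' spent on it, signed so that sinking is negative: with depths positive
#' downward, `Dr = -(D_end - D_start) / (T_end - T_start)`.  A negatively
#' buoyant (lean) seal sinks during the drift phase and has `Dr < 0`.
#'
#' @param summary one row of a summarized-dive table.
#' @param segment segment index in `1:3`; segment `i` joins `IFP_i` to
#'   `IFP_{i+1}`.  The descent (segment 0) and final ascent (segment 4)
#'   are never drift segments.
#' @return signed drift rate in m/s.
#' @export
compute_drift_rate <- function(summary, segment) {
  if (!segment %in% 1:3) stop("drift segment must be 1, 2 or 3")
  s <- as.list(summary[1L, ])
  Ts <- c(s$T1, s$T2, s$T3, s$T4)
  Ds <- c(s$D1, s$D2, s$D3, s$D4)
  dt <- Ts[segment + 1L] - Ts[segment]
  if (dt <= 0) stop("degenerate segment (zero duration) in dive ", s$dive_id)
  -(Ds[segment + 1L] - Ds[segment]) / dt
}
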