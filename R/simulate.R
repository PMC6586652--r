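#' Synthetic trip configuration
#'
#' Settings for the synthetic seal-trip generator, which produces
#' high-resolution dives with known labels, known drift segments and a
#' known, slowly varying daily buoyancy trajectory.  Defaults emulate a
#' deep-diving phocid trip: 30 s depth sampling, about 6% drift dives, a
#' trip-start buoyancy of -0.3 m/s improving steadily as the animal
#' feeds (crossing zero late in a 60-day trip), short shallow exploratory
#' dives that the preprocessing filters must remove, and a fraction of
#' "drift-mimic" dives whose summarized form resembles a drift dive but
#' whose vertical rate is unrelated to the buoyancy trajectory.
#'
#' Drift dives are built from three phases: an active descent, a passive
#' drift phase whose slope equals the day's buoyancy plus per-dive jitter,
#' and an active return to the surface.  Active phases carry sinusoidal
#' "wiggles" (directional changes from stroking and prey pursuit), while
#' the drift phase is smooth; for a negatively buoyant seal the descent is
#' a partial glide (small wiggles) and the ascent is worked (larger
#' wiggles, slow deep phase then a faster surface phase), and vice versa
#' for a positively buoyant seal, which glides up and strokes down.
#'
#' @param n_days trip length in days.
#' @param dives_per_day dives per day.
#' @param drift_fraction fraction of dives that are true drift dives.
#' @param mimic_fraction fraction of drift-mimicking non-drift dives.
#' @param exploratory_fraction fraction of short shallow exploratory
#'   dives (filter bait: max depth < 100 m and duration < 300 s).
#' @param sampling_interval depth sampling interval (s).
#' @param depth_range range (m) of the drift-phase start depth.
#' @param buoyancy_initial day-1 buoyancy (vertical drift rate, m/s;
#'   negative = sinking).
#' @param buoyancy_increment daily buoyancy increment (m/s per day).  The
#'   default schedule spans the early-trip recovery of a lean animal
#'   (-0.3 to about -0.06 m/s over 60 days); larger increments or longer
#'   trips make the trajectory cross zero, after which drift dives are
#'   positive (rising).
#' @param drift_rate_jitter SD (m/s) of per-dive drift-rate jitter around
#'   the daily buoyancy.
#' @param drift_noise_sd SD (m) of depth noise on the drift phase.
#' @param wiggle_amp range (m) of active-phase wiggle amplitudes.
#' @param emit_velocity also emit a synthetic swim-speed channel (small
#'   during drift, larger during active phases); unused by the pipeline.
#' @param trip_start absolute `POSIXct` start of the trip (UTC).
#' @param seed integer seed; the whole trip is reproducible from it.
#' @return an object of class `trip_config` (a validated list).
#' @export
trip_config <- function(n_days = 60, dives_per_day = 50,
                        drift_fraction = 0.06, mimic_fraction = 0.05,
                        exploratory_fraction = 0.10,
                        sampling_interval = 30,
                        depth_range = c(200, 450),
                        buoyancy_initial = -0.3,
                        buoyancy_increment = 0.004,
                        drift_rate_jitter = 0.02,
                        drift_noise_sd = 0.7,
                        wiggle_amp = c(1, 5),
                        emit_velocity = FALSE,
                        trip_start = as.POSIXct("2004-01-01 00:00:00",
                                                tz = "UTC"),
                        seed = 1L) {
  fr <- c(drift_fraction, mimic_fraction, exploratory_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("dive-kind fractions must lie in [0, 1] and sum to at most 1")
  if (sampling_interval <= 0) stop("sampling_interval must be > 0")
  if (n_days < 1) stop("n_days must be >= 1")
  if (depth_range[1L] < 100)
    stop("drift dives must start deeper than the 100 m preprocessing bound")
  structure(list(n_days = n_days, dives_per_day = dives_per_day,
                 drift_fraction = drift_fraction,
                 mimic_fraction = mimic_fraction,
                 exploratory_fraction = exploratory_fraction,
                 sampling_interval = sampling_interval,
                 depth_range = depth_range,
                 buoyancy_initial = buoyancy_initial,
                 buoyancy_increment = buoyancy_increment,
                 drift_rate_jitter = drift_rate_jitter,
                 drift_noise_sd = drift_noise_sd,
                 wiggle_amp = wiggle_amp,
                 emit_velocity = emit_velocity,
                 trip_start = trip_start, seed = as.integer(seed)),
            class = "trip_config")
}

# evaluate a piecewise-linear path given breakpoints (t, d) at times tt
.path_depth <- function(bk_t, bk_d, tt) .pw_interp(bk_t, bk_d, tt)

# sinusoidal wiggle confined to [t0, t1], zero amplitude at the ends
.wiggle <- function(tt, t0, t1, amp, period, phase) {
  w <- amp * sin(2 * pi * (tt - t0) / period + phase)
  taper <- pmax(0, pmin(1, pmin(tt - t0, t1 - tt) / (0.15 * (t1 - t0))))
  ifelse(tt >= t0 & tt <= t1, w * taper, 0)
}

.runif1 <- function(lo, hi) stats::runif(1L, lo, hi)

# one synthetic dive; returns list(times, depths, velocity, seg (s), kind)
.dive_shape <- function(kind, cfg, b_dive) {
  wa <- cfg$wiggle_amp
  if (kind == "drift" && b_dive >= 0) kind <- "drift_pos"
  if (kind == "drift") {                     # negative (sinking) drift
    d0 <- .runif1(cfg$depth_range[1L], cfg$depth_range[2L])
    desc_rate <- .runif1(1.8, 2.5)
    # about half the dives brake over the last part of the descent,
    # leaving a marked inflection before the drift begins
    if (stats::runif(1) < 0.5) {
      qd <- .runif1(0.55, 0.8)
      v2 <- .runif1(0.8, 1.4)
      td <- qd * d0 / desc_rate
      t1 <- td + (1 - qd) * d0 / v2
      desc_bk_t <- c(0, td, t1)
      desc_bk_d <- c(0, qd * d0, d0)
    } else {
      t1 <- d0 / desc_rate
      desc_bk_t <- c(0, t1)
      desc_bk_d <- c(0, d0)
    }
    dur <- 2.4 * d0 + .runif1(100, 400)
    dmax <- d0 - b_dive * dur                # b_dive <= 0: sinks to dmax
    # ascent: either a steady climb or a worked two-phase climb (slow over
    # the deeper part, then faster towards the surface), leaving a marked
    # inflection in the upper-middle water column
    q <- .runif1(0.45, 0.7)
    if (stats::runif(1) < 0.5) {
      u1 <- .runif1(0.5, 1.2)
      u2 <- .runif1(1.3, 2.1)
    } else {
      u1 <- u2 <- .runif1(0.8, 1.8)
    }
    t2 <- t1 + dur
    t3 <- t2 + dmax * (1 - q) / u1
    t4 <- t3 + q * dmax / u2
    bk_t <- c(desc_bk_t, t2, t3, t4)
    bk_d <- c(desc_bk_d, dmax, q * dmax, 0)
    E <- t4
    tt <- unique(c(seq(0, E, by = cfg$sampling_interval), E))
    dd <- .path_depth(bk_t, bk_d, tt)
    dd <- dd +
      .wiggle(tt, 0, t1, .runif1(0.5, 0.4 * wa[2L]), .runif1(80, 140),
              stats::runif(1, 0, 2 * pi)) +
      .wiggle(tt, t2, t4, .runif1(wa[1L], wa[2L]), .runif1(80, 140),
              stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(length(tt), 0,
                   ifelse(tt > t1 & tt < t2, cfg$drift_noise_sd, 0.4))
    seg <- c(t1, t2)
  } else if (kind == "drift_pos") {          # positive (rising) drift
    d0 <- .runif1(cfg$depth_range[1L], cfg$depth_range[2L]) + 100
    desc_rate <- .runif1(1.5, 2.2)
    t1 <- d0 / desc_rate
    dur <- 2.0 * d0 + .runif1(100, 400)
    if (b_dive > 0) dur <- min(dur, 0.8 * d0 / b_dive)
    dend <- d0 - b_dive * dur                # rises towards the surface
    u <- .runif1(0.9, 1.5)
    t2 <- t1 + dur
    t3 <- t2 + dend / u
    bk_t <- c(0, t1, t2, t3)
    bk_d <- c(0, d0, dend, 0)
    E <- t3
    tt <- unique(c(seq(0, E, by = cfg$sampling_interval), E))
    dd <- .path_depth(bk_t, bk_d, tt)
    dd <- dd +
      .wiggle(tt, 0, t1, .runif1(wa[1L], wa[2L]), .runif1(80, 140),
              stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(length(tt), 0,
                   ifelse(tt > t1 & tt < t2, cfg$drift_noise_sd, 0.3))
    seg <- c(t1, t2)
  } else if (kind == "mimic") {              # drift-lookalike, rate unrelated
    d0 <- .runif1(cfg$depth_range[1L], cfg$depth_range[2L])
    slope <- .runif1(-0.6, 0.6)
    desc_rate <- .runif1(1.8, 2.5)
    t1 <- d0 / desc_rate
    dur <- .runif1(400, 900)
    dend <- max(d0 + slope * dur, 0.3 * d0)
    dmax <- max(d0, dend)
    q <- .runif1(0.65, 0.85)
    t2 <- t1 + dur
    t3 <- t2 + dend * (1 - q) / .runif1(0.4, 0.8)
    t4 <- t3 + q * dend / .runif1(1.4, 2.0)
    bk_t <- c(0, t1, t2, t3, t4)
    bk_d <- c(0, d0, dend, q * dend, 0)
    E <- t4
    tt <- unique(c(seq(0, E, by = cfg$sampling_interval), E))
    dd <- .path_depth(bk_t, bk_d, tt)
    dd <- dd +
      .wiggle(tt, t1, t2, .runif1(1.5, 4), .runif1(100, 200),
              stats::runif(1, 0, 2 * pi)) +
      .wiggle(tt, t2, t4, .runif1(wa[1L], wa[2L]), .runif1(80, 140),
              stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(length(tt), 0, 0.5)
    seg <- NULL
  } else if (kind == "vshape") {
    dmax <- .runif1(250, 650)
    rd <- .runif1(0.9, 1.6)
    ra <- .runif1(0.8, 1.4)
    t1 <- dmax / rd
    E <- t1 + dmax / ra
    tt <- unique(c(seq(0, E, by = cfg$sampling_interval), E))
    dd <- .path_depth(c(0, t1, E), c(0, dmax, 0), tt) +
      stats::rnorm(length(tt), 0, 0.5)
    seg <- NULL
  } else if (kind == "ushape") {
    dmax <- .runif1(200, 550)
    rd <- .runif1(1.2, 2.0)
    ra <- .runif1(1.2, 2.0)
    bdur <- .runif1(400, 1100)
    bslope <- .runif1(-0.05, 0.05)
    t1 <- dmax / rd
    t2 <- t1 + bdur
    dend <- dmax + bslope * bdur
    E <- t2 + dend / ra
    tt <- unique(c(seq(0, E, by = cfg$sampling_interval), E))
    dd <- .path_depth(c(0, t1, t2, E), c(0, dmax, dend, 0), tt) +
      .wiggle(tt, t1, t2, .runif1(8, 25), .runif1(100, 200),
              stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(length(tt), 0, 1)
    seg <- NULL
  } else if (kind == "exploratory") {        # filter bait: shallow and short
    dmax <- .runif1(30, 90)
    rd <- .runif1(0.8, 1.5)
    ra <- .runif1(0.8, 1.5)
    t1 <- dmax / rd
    E <- t1 + dmax / ra
    tt <- unique(c(seq(0, E, by = cfg$sampling_interval), E))
    if (length(tt) < 4L) tt <- seq(0, E, length.out = 4L)
    dd <- .path_depth(c(0, t1, E), c(0, dmax, 0), tt) +
      stats::rnorm(length(tt), 0, 0.3)
    seg <- NULL
  } else stop("unknown dive kind: ", kind)
  dd[c(1L, length(dd))] <- 0                 # surface at the endpoints
  dd <- pmax(dd, 0)
  vel <- if (cfg$emit_velocity) {
    active <- if (is.null(seg)) rep(TRUE, length(tt))
    else !(tt > seg[1L] & tt < seg[2L])
    ifelse(active, stats::rnorm(length(tt), 1.5, 0.2),
           abs(stats::rnorm(length(tt), 0.1, 0.05)))
  } else NULL
  list(times = tt, depths = dd, velocity = vel, seg = seg, kind = kind)
}

#' Simulate a single dive
#'
#' Draws one synthetic dive of the requested kind.  Drift dives take the
#' three-phase form (descent, passive drift at `b_dive` m/s, return to the
#' surface); `vshape`/`ushape` dives are transit and foraging shapes with
#' wiggles; `mimic` dives are non-drift dives whose summarized form
#' resembles a drift dive; `exploratory` dives are shallow and short and
#' must be removed by [preprocess_filter()].
#'
#' @param kind one of `"drift"`, `"vshape"`, `"ushape"`, `"mimic"`,
#'   `"exploratory"`.
#' @param config a [trip_config()] providing shape parameter ranges.
#' @param b_dive drift rate (m/s, negative = sinking) for drift dives.
#' @param dive_id identifier for the generated profile.
#' @param start_datetime optional absolute dive start.
#' @param seed optional integer seed (set for a reproducible single dive).
#' @return list with `profile` (an [high_res_profile()]) and `label`
#'   (data.frame: `dive_id`, `kind`, `label`, `sign`, `seg_start`,
#'   `seg_end` — sample index range of the true drift segment — and
#'   `b_true`).
#' @export
simulate_dive <- function(kind, config = trip_config(), b_dive = -0.25,
                          dive_id = "d1", start_datetime = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sh <- .dive_shape(kind, config, b_dive)
  prof <- high_res_profile(dive_id, sh$times, sh$depths,
                           velocity = sh$velocity,
                           start_datetime = start_datetime)
  is_drift <- sh$kind %in% c("drift", "drift_pos")
  if (is_drift) {
    idx <- which(prof$times >= sh$seg[1L] & prof$times <= sh$seg[2L])
    seg_start <- idx[1L]
    seg_end <- idx[length(idx)]
    if (length(idx) < 2L) stop("drift phase shorter than 2 samples")
  } else seg_start <- seg_end <- NA_integer_
  label <- data.frame(
    dive_id = dive_id, kind = kind,
    label = if (is_drift) "drift_certain" else "non_drift",
    sign = if (!is_drift) "none" else if (b_dive >= 0) "positive"
    else "negative",
    seg_start = seg_start, seg_end = seg_end,
    b_true = if (is_drift) b_dive else NA_real_,
    stringsAsFactors = FALSE)
  list(profile = prof, label = label)
}

#' Simulate a full trip
#'
#' Generates `n_days * dives_per_day` dives with kinds drawn from the
#' configured fractions (the remainder split evenly between V- and
#' U-shaped dives), a daily buoyancy trajectory
#' `b(day) = buoyancy_initial + buoyancy_increment * (day - 1)` (which may
#' cross zero), and per-dive drift rates jittered around the day's
#' buoyancy.  Fully reproducible from `config$seed`.
#'
#' @param config a [trip_config()].
#' @return list with `profiles` (named list of [high_res_profile()]),
#'   `labels` (one row per dive: kind, label, sign, true segment sample
#'   range, true per-dive drift rate, `date`), and `truth`
#'   (data.frame: `day`, `date`, daily `buoyancy` in m/s).
#' @export
simulate_trip <- function(config = trip_config()) {
  stopifnot(inherits(config, "trip_config"))
  set.seed(config$seed)
  n <- config$n_days * config$dives_per_day
  gap <- 86400 / config$dives_per_day
  profiles <- vector("list", n)
  labels <- vector("list", n)
  k <- 0L
  for (day in seq_len(config$n_days)) {
    b_day <- config$buoyancy_initial + config$buoyancy_increment * (day - 1)
    for (j in seq_len(config$dives_per_day)) {
      k <- k + 1L
      id <- sprintf("d%05d", k)
      u <- stats::runif(1)
      kind <- if (u < config$drift_fraction) "drift"
      else if (u < config$drift_fraction + config$mimic_fraction) "mimic"
      else if (u < config$drift_fraction + config$mimic_fraction +
               config$exploratory_fraction) "exploratory"
      else if (stats::runif(1) < 0.5) "vshape" else "ushape"
      b_dive <- b_day + stats::rnorm(1, 0, config$drift_rate_jitter)
      start <- config$trip_start + ((day - 1) * 86400 + (j - 1) * gap)
      sd <- simulate_dive(kind, config, b_dive = b_dive, dive_id = id,
                          start_datetime = start)
      profiles[[k]] <- sd$profile
      lab <- sd$label
      lab$date <- as.Date(start)
      labels[[k]] <- lab
    }
  }
  names(profiles) <- vapply(profiles, function(p) p$dive_id, character(1))
  truth <- data.frame(
    day = seq_len(config$n_days),
    date = as.Date(config$trip_start) + seq_len(config$n_days) - 1L,
    buoyancy = config$buoyancy_initial +
      config$buoyancy_increment * (seq_len(config$n_days) - 1L))
  list(profiles = profiles, labels = do.call(rbind, labels), truth = truth)
}
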