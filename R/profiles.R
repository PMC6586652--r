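#' High-resolution dive profile
#'
#' Container for a single dive's time-depth record as sampled by an archival
#' tag (typically at 30 s intervals).  Depths are metres, positive downward;
#' times are seconds since the start of the dive.
#'
#' @param dive_id character or integer identifier, unique within a trip.
#' @param times numeric vector of sample times (s since dive start),
#'   strictly increasing.
#' @param depths numeric vector of sample depths (m, positive down), same
#'   length as `times`.
#' @param velocity optional numeric vector of swim speeds (m/s) per sample.
#'   Carried through but unused by the detection pipeline.
#' @param start_datetime optional `POSIXct` absolute start time of the dive,
#'   used only for daily binning of drift rates.
#' @param surface_threshold maximum depth (m) allowed for the first and last
#'   sample; a dive record must begin and end at the surface.
#'
#' @return An object of class `hr_profile`: a list with the validated fields.
#' @examples
#' p <- high_res_profile("d1", times = c(0, 30, 60, 90),
#'                       depths = c(0, 120, 110, 0))
#' max(p$depths)
#' @export
high_res_profile <- function(dive_id, times, depths, velocity = NULL,
                             start_datetime = NULL, surface_threshold = 2) {
  if (length(times) != length(depths))
    stop("times and depths must have equal length (dive ", dive_id, ")")
  if (length(times) < 3L)
    stop("profile needs at least 3 samples (dive ", dive_id, ")")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing (dive ", dive_id, ")")
  if (any(depths < 0))
    stop("depths must be non-negative (positive-down convention; dive ",
         dive_id, ")")
  if (depths[1L] > surface_threshold || depths[length(depths)] > surface_threshold)
    stop("first and last depth must be at the surface (<= ",
         surface_threshold, " m; dive ", dive_id, ")")
  if (!is.null(velocity) && length(velocity) != length(times))
    stop("velocity must match sample length (dive ", dive_id, ")")
  structure(list(dive_id = as.character(dive_id),
                 times = as.numeric(times),
                 depths = as.numeric(depths),
                 velocity = velocity,
                 start_datetime = start_datetime),
            class = "hr_profile")
}

#' @export
print.hr_profile <- function(x, ...) {
  cat("<hr_profile> dive", x$dive_id, "-", length(x$times), "samples,",
      "max depth", round(max(x$depths), 1), "m, duration",
      round(x$times[length(x$times)] - x$times[1L]), "s\n")
  invisible(x)
}

#' Dive duration in seconds
#' @param profile an `hr_profile`.
#' @return numeric scalar, seconds between first and last sample.
#' @export
dive_duration <- function(profile) {
  profile$times[length(profile$times)] - profile$times[1L]
}

#' Read high-resolution dive profiles from a delimited file
#'
#' One row per sample.  Column names are resolved through `col_map`, so
#' arbitrary tabular exports can be read without renaming.
#'
#' @param path path to a CSV/TSV file.
#' @param col_map named list mapping the roles `dive_id`, `time`, `depth`
#'   and optionally `velocity`, `start_datetime` to column names in the file.
#' @param sep field separator (default comma).
#' @param depth_positive_down set `FALSE` when the file stores depth in the
#'   negative-down convention; depths are negated on read so that they are
#'   stored positive-down.
#' @return a named list of [high_res_profile()] objects, one per dive id,
#'   in order of first appearance.
#' @export
load_profiles <- function(path,
                          col_map = list(dive_id = "dive_id", time = "time",
                                         depth = "depth"),
                          sep = ",", depth_positive_down = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty profile file: ", path)
  need <- c("dive_id", "time", "depth")
  for (role in need) {
    cn <- col_map[[role]]
    if (is.null(cn) || !cn %in% names(df))
      stop("column for '", role, "' not found in ", path)
  }
  ids <- as.character(df[[col_map$dive_id]])
  depths <- df[[col_map$depth]]
  if (!depth_positive_down) depths <- -depths
  out <- list()
  for (id in unique(ids)) {
    sel <- ids == id
    tt <- df[[col_map$time]][sel]
    if (any(diff(tt) <= 0))
      stop("non-monotone or duplicated times in dive ", id)
    vel <- if (!is.null(col_map$velocity) && col_map$velocity %in% names(df))
      df[[col_map$velocity]][sel] else NULL
    sd0 <- if (!is.null(col_map$start_datetime) &&
               col_map$start_datetime %in% names(df))
      as.POSIXct(df[[col_map$start_datetime]][sel][1L], tz = "UTC") else NULL
    out[[id]] <- high_res_profile(id, tt, depths[sel], velocity = vel,
                                  start_datetime = sd0)
  }
  out
}

#' Write high-resolution dive profiles to a delimited file
#'
#' Inverse of [load_profiles()]: times and depths round-trip exactly at
#' double precision.
#'
#' @param profiles list of `hr_profile` objects.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, sep = ",") {
  rows <- lapply(profiles, function(p) {
    data.frame(dive_id = p$dive_id, time = p$times, depth = p$depths,
               start_datetime = if (is.null(p$start_datetime)) NA_character_
               else format(p$start_datetime, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pre-detection dive filters
#'
#' Removes shallow and short dives before drift-dive detection: dives must
#' reach a minimum depth (default 100 m, avoiding buoyancy bias from
#' residual air in the lungs) and last a minimum duration (default 300 s,
#' excluding short exploratory dives).  The depth bound is inclusive
#' (exactly 100 m is retained); the duration bound removes dives strictly
#' shorter than 300 s.
#'
#' Applies to either a list of high-resolution profiles or a summarized
#' dive table (then using the transmitted `max_depth` and `E` columns).
#'
#' @param dives list of `hr_profile` objects, or a summarized-dive
#'   `data.frame` as produced by [summarize_dives()].
#' @param min_depth minimum maximum-depth in metres (retained if `>=`).
#' @param min_duration minimum dive duration in seconds (rejected if `<`).
#' @return list with `retained` (same container type as the input) and
#'   `log`, a data.frame of rejected dive ids and the reason
#'   (`"depth"` or `"duration"`).
#' @export
preprocess_filter <- function(dives, min_depth = 100, min_duration = 300) {
  if (is.data.frame(dives)) {
    deep <- dives$max_depth >= min_depth
    long <- dives$E >= min_duration
    ids <- as.character(dives$dive_id)
  } else {
    deep <- vapply(dives, function(p) max(p$depths) >= min_depth, logical(1))
    long <- vapply(dives, function(p) dive_duration(p) >= min_duration,
                   logical(1))
    ids <- vapply(dives, function(p) p$dive_id, character(1))
  }
  keep <- deep & long
  reason <- ifelse(!deep, "depth", "duration")
  log <- data.frame(dive_id = ids[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  retained <- if (is.data.frame(dives)) dives[keep, , drop = FALSE]
  else dives[keep]
  list(retained = retained, log = log)
}
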