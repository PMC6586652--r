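#' Summarized-dive table schema
#'
#' A summarized dive is the 6-point abstraction transmitted by a
#' satellite-relay tag: the dive start `{0, 0}`, four subsurface inflection
#' points `IFP1..IFP4` at times `T1 < T2 < T3 < T4` with depths `D1..D4`
#' (sorted by time of occurrence, not selection order), and the dive end
#' `{E, 0}`.  Tables of summarized dives use one row per dive with columns:
#'
#' `dive_id`, `start_datetime`, `E`, `T1..T4`, `D1..D4`, `max_depth`,
#' `res1..res4` (broken-stick residuals in selection order, when known) and
#' optionally `order` (the dotted selection-order label).
#'
#' @param dive_id identifier.
#' @param times numeric length-4, inflection point times (s), strictly
#'   increasing and strictly inside `(0, E)`.
#' @param depths numeric length-4, inflection point depths (m, positive
#'   down).
#' @param E dive duration (s).
#' @param residuals optional numeric length-4, broken-stick residual
#'   magnitudes (m) in selection order.
#' @param order optional dotted selection-order label such as `"2.1.3.4"`.
#' @param start_datetime optional `POSIXct` dive start.
#' @return one-row `data.frame` in the summarized-dive schema.
#' @export
summarized_dive <- function(dive_id, times, depths, E, residuals = NULL,
                            order = NA_character_, start_datetime = NULL) {
  stopifnot(length(times) == 4L, length(depths) == 4L)
  if (any(diff(times) <= 0))
    stop("inflection point times must be strictly increasing (dive ",
         dive_id, ")")
  if (times[1L] <= 0 || times[4L] >= E)
    stop("inflection points must lie strictly inside (0, E) (dive ",
         dive_id, ")")
  if (any(depths < 0)) stop("depths must be >= 0 (dive ", dive_id, ")")
  if (!is.null(residuals)) {
    stopifnot(length(residuals) == 4L)
    if (any(residuals < 0)) stop("residuals must be >= 0")
  } else residuals <- rep(NA_real_, 4L)
  out <- data.frame(dive_id = as.character(dive_id),
                    start_datetime = if (is.null(start_datetime))
                      as.POSIXct(NA) else start_datetime,
                    E = as.numeric(E),
                    stringsAsFactors = FALSE)
  out[paste0("T", 1:4)] <- as.list(as.numeric(times))
  out[paste0("D", 1:4)] <- as.list(as.numeric(depths))
  out$max_depth <- max(depths)
  out[paste0("res", 1:4)] <- as.list(as.numeric(residuals))
  out$order <- order
  out
}

#' Six summary points of a summarized dive
#'
#' @param summary one row of a summarized-dive table.
#' @return a 6 x 2 matrix with columns `time`, `depth`: start, IFP1..IFP4,
#'   end.
#' @export
summary_points <- function(summary) {
  summary <- as.list(summary[1L, ])
  m <- cbind(time = c(0, summary$T1, summary$T2, summary$T3, summary$T4,
                      summary$E),
             depth = c(0, summary$D1, summary$D2, summary$D3, summary$D4, 0))
  rownames(m) <- c("start", paste0("IFP", 1:4), "end")
  m
}

#' Read and write summarized-dive tables
#'
#' The on-disk format is delimited text in the schema documented at
#' [summarized_dive()].  `read_summaries()` validates each row.
#'
#' @param path file path.
#' @param sep field separator.
#' @return `read_summaries()`: a validated summarized-dive `data.frame`.
#' @export
read_summaries <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("dive_id", "E", paste0("T", 1:4), paste0("D", 1:4), "max_depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("summarized-dive table missing columns: ",
         paste(miss, collapse = ", "))
  if ("start_datetime" %in% names(df))
    df$start_datetime <- as.POSIXct(df$start_datetime, tz = "UTC",
                                    format = "%Y-%m-%dT%H:%M:%S")
  for (i in seq_len(nrow(df))) {
    tt <- as.numeric(df[i, paste0("T", 1:4)])
    if (any(diff(tt) <= 0) || tt[1L] <= 0 || tt[4L] >= df$E[i])
      stop("invalid inflection point times in dive ", df$dive_id[i])
  }
  df
}

#' @rdname read_summaries
#' @param summaries summarized-dive `data.frame`.
#' @export
write_summaries <- function(summaries, path, sep = ",") {
  df <- summaries
  if ("start_datetime" %in% names(df))
    df$start_datetime <- format(df$start_datetime, "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
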