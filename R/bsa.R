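# piecewise-linear reconstruction through a set of (time, depth) nodes
.pw_interp <- function(t_nodes, d_nodes, t_out) {
  o <- order(t_nodes)
  stats::approx(t_nodes[o], d_nodes[o], xout = t_out, method = "linear",
                rule = 2)$y
}

#' Broken-stick summarization of a high-resolution dive
#'
#' Greedy piecewise-linear abstraction reproducing the on-board processing
#' of satellite-relay tags.  The first interior point selected is the
#' deepest sample (largest departure from the surface); each subsequent
#' point is the sample with the largest absolute depth discrepancy from the
#' piecewise-linear reconstruction through the start, end, and
#' already-selected points.  Ties are broken by earliest time.  The maximal
#' discrepancy at each step is recorded as that step's residual.
#'
#' @param profile an [high_res_profile()].
#' @param n_subsurface number of interior inflection points to keep
#'   (transmitted tags keep 4).
#' @param interp abscissa used by the reconstruction: `"time"` interpolates
#'   in seconds (the default), `"index"` in sample index, mimicking
#'   firmware that ignores irregular sampling.
#' @return an object of class `bsa_result`: list with `summary` (one-row
#'   summarized-dive table, inflection points sorted by time, `order` label
#'   filled in), `selection_order` (integer permutation: position of each
#'   selected point among the time-sorted labels), `residuals` (m, in
#'   selection order) and `indices` (sample indices selected, in selection
#'   order).
#' @examples
#' p <- high_res_profile("d1", times = seq(0, 600, by = 30),
#'                       depths = c(0, seq(30, 300, length.out = 9),
#'                                  seq(280, 20, length.out = 10), 0))
#' bsa_summarize(p)$summary$order
#' @export
bsa_summarize <- function(profile, n_subsurface = 4,
                          interp = c("time", "index")) {
  interp <- match.arg(interp)
  tt <- if (interp == "time") profile$times else seq_along(profile$times)
  dd <- profile$depths
  n <- length(tt)
  if (n < n_subsurface + 2L)
    stop("profile has too few samples for ", n_subsurface,
         " inflection points (dive ", profile$dive_id, ")")
  interior <- 2:(n - 1L)
  nodes <- c(1L, n)                      # start + end always in the recon
  sel <- integer(0)
  res <- numeric(0)
  for (k in seq_len(n_subsurface)) {
    cand <- setdiff(interior, sel)
    if (k == 1L) {
      # deepest sample: highest difference from the surface line
      i <- cand[which.max(dd[cand])]
      disc <- abs(dd[i] - .pw_interp(tt[nodes], dd[nodes], tt[i]))
    } else {
      recon <- .pw_interp(tt[c(nodes, sel)], dd[c(nodes, sel)], tt[cand])
      d_abs <- abs(dd[cand] - recon)
      i <- cand[which.max(d_abs)]        # which.max: earliest-time tie-break
      disc <- max(d_abs)
    }
    sel <- c(sel, i)
    res <- c(res, disc)
  }
  time_sorted <- sort(sel)
  selection_order <- match(sel, time_sorted)
  real_t <- profile$times - profile$times[1L]  # summary times from dive start
  smry <- summarized_dive(profile$dive_id,
                          times = real_t[time_sorted],
                          depths = dd[time_sorted],
                          E = real_t[n] - real_t[1L],
                          residuals = res,
                          order = paste(selection_order, collapse = "."),
                          start_datetime = profile$start_datetime)
  structure(list(summary = smry, selection_order = selection_order,
                 residuals = res, indices = sel),
            class = "bsa_result")
}

#' Summarize a collection of dives into one table
#'
#' @param profiles list of `hr_profile` objects.
#' @param ... passed to [bsa_summarize()].
#' @return summarized-dive `data.frame`, one row per dive, with the `order`
#'   column recording the true selection order.
#' @export
summarize_dives <- function(profiles, ...) {
  do.call(rbind, lapply(profiles, function(p) bsa_summarize(p, ...)$summary))
}

#' Depth of the summarized profile at an arbitrary time
#'
#' Linear interpolation between the two bracketing summary points; exact at
#' the six transmitted points.
#'
#' @param summary one row of a summarized-dive table.
#' @param t time(s) in seconds since dive start, within `[0, E]`.
#' @return interpolated depth(s) in metres.
#' @export
reconstruct_depth <- function(summary, t) {
  pts <- summary_points(summary)
  if (any(t < 0 | t > summary$E[1L]))
    stop("t outside [0, E] for dive ", summary$dive_id[1L])
  .pw_interp(pts[, "time"], pts[, "depth"], t)
}
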