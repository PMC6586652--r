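#' Reverse broken-stick algorithm: recover the selection order
#'
#' From a transmitted 6-point summary alone, recovers the order in which
#' the on-board broken-stick algorithm selected the four subsurface
#' inflection points, and regenerates the residual magnitudes.  The only
#' point whose selection position is known a priori is the deepest point —
#' necessarily selected first.  A linear profile is then reconstructed
#' between the selected points and the dive's start and end, and at each
#' step the remaining transmitted point with the largest absolute depth
#' discrepancy from the reconstruction is taken as the next selection.
#' Discrepancies are measured only at the transmitted points (the
#' high-resolution series is unavailable by construction); ties are broken
#' by earliest time, mirroring [bsa_summarize()].
#'
#' The last recovered residual — the largest remaining difference between
#' the summarized point set and its 3-point reconstruction — indicates the
#' amount of vertical activity not captured by the summary.
#'
#' @param summary one row of a summarized-dive table.
#' @return an object of class `ifp_order`: list with `label` (dotted
#'   string over time-sorted point indices, e.g. `"2.1.3.4"`), `order`
#'   (integer permutation of 1:4 in selection order) and `residuals`
#'   (recovered residual magnitudes, m, in selection order).
#' @examples
#' s <- summarized_dive("d1", times = c(120, 700, 800, 880),
#'                      depths = c(250, 340, 220, 100), E = 950)
#' recover_order(s)$label
#' @export
recover_order <- function(summary) {
  pts <- summary_points(summary)
  ifp_t <- unname(pts[2:5, "time"])
  ifp_d <- unname(pts[2:5, "depth"])
  if (sum(ifp_d == max(ifp_d)) > 1L)
    warning("duplicate maximum depth among inflection points of dive ",
            summary$dive_id[1L], "; earliest taken as first selected")
  nodes_t <- pts[c(1L, 6L), "time"]
  nodes_d <- pts[c(1L, 6L), "depth"]
  sel <- integer(0)
  res <- numeric(0)
  for (k in 1:4) {
    cand <- setdiff(1:4, sel)
    if (k == 1L) {
      i <- cand[which.max(ifp_d[cand])]
      disc <- abs(ifp_d[i] - .pw_interp(nodes_t, nodes_d, ifp_t[i]))
    } else {
      recon <- .pw_interp(c(nodes_t, ifp_t[sel]), c(nodes_d, ifp_d[sel]),
                          ifp_t[cand])
      d_abs <- abs(ifp_d[cand] - recon)
      i <- cand[which.max(d_abs)]
      disc <- max(d_abs)
    }
    sel <- c(sel, i)
    res <- c(res, disc)
  }
  structure(list(label = paste(sel, collapse = "."), order = sel,
                 residuals = res),
            class = "ifp_order")
}

#' @export
print.ifp_order <- function(x, ...) {
  cat("<ifp_order>", x$label, "- residuals (m):",
      paste(round(x$residuals, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Annotate a summarized-dive table with recovered selection orders
#'
#' Runs [recover_order()] on each row and appends an `ifp_order` column and
#' `res_last`, the final recovered residual (vertical-activity indicator).
#' Recovered residuals in selection order are stored in `res1..res4`
#' whenever the table does not already carry on-board residuals.
#'
#' @param summaries summarized-dive `data.frame`.
#' @return the table with `ifp_order` and `res_last` columns added.
#' @export
add_orders <- function(summaries) {
  orders <- character(nrow(summaries))
  res_last <- numeric(nrow(summaries))
  res_mat <- matrix(NA_real_, nrow(summaries), 4L)
  for (i in seq_len(nrow(summaries))) {
    o <- recover_order(summaries[i, , drop = FALSE])
    orders[i] <- o$label
    res_last[i] <- o$residuals[4L]
    res_mat[i, ] <- o$residuals
  }
  summaries$ifp_order <- orders
  summaries$res_last <- res_last
  if (!"res1" %in% names(summaries) || all(is.na(summaries$res1))) {
    summaries[paste0("res", 1:4)] <- as.data.frame(res_mat)
  }
  summaries
}
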