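#' Drift-segment assignment rules
#'
#' The drifting segment of a candidate dive is located by a small set of
#' declarative per-group rules: ordered predicates over the dive-shape
#' variables, each naming the segment (1-3) assigned when it fires first.
#' The rules ship as an editable delimited file rather than hard-coded
#' logic, so that alternative transcriptions or refinements can be swapped
#' in; each group ends in a documented fallback (`predicate == "TRUE"`).
#'
#' @param path path to a rules file; defaults to the file bundled with the
#'   package.
#' @return `data.frame` with columns `group`, `priority`, `segment`,
#'   `predicate` (an R expression over shape-variable names) and `note`.
#' @export
load_segment_rules <- function(path = system.file("extdata",
                                                  "segment_rules.csv",
                                                  package = "driftdive")) {
  rules <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("group", "priority", "segment", "predicate")
  miss <- setdiff(need, names(rules))
  if (length(miss))
    stop("segment rules file missing columns: ", paste(miss, collapse = ", "))
  if (!all(rules$segment %in% 1:3))
    stop("segment rules may only assign segments 1-3")
  rules[order(rules$group, rules$priority), ]
}

#' Assign the drifting segment of a candidate dive
#'
#' Evaluates the group's rules in priority order against the dive's shape
#' variables; the first predicate that fires determines the segment.
#'
#' @param group group label (must appear in the rules).
#' @param vars one-row `data.frame` of shape variables from
#'   [compute_shape_variables()].
#' @param rules rules table from [load_segment_rules()].
#' @return segment index in `1:3`, with attribute `"rule"` giving the
#'   priority of the rule that fired; `NA` when the dive is degenerate or
#'   no rule (including the fallback) fires.
#' @export
assign_drift_segment <- function(group, vars,
                                 rules = load_segment_rules()) {
  if (isTRUE(vars$degenerate)) return(NA_integer_)
  rr <- rules[rules$group == group, , drop = FALSE]
  if (nrow(rr) == 0L) stop("no segment rules for group ", group)
  env <- list2env(as.list(vars[1L, ]))
  for (i in seq_len(nrow(rr))) {
    hit <- eval(parse(text = rr$predicate[i]), envir = env)
    if (isTRUE(hit))
      return(structure(as.integer(rr$segment[i]), rule = rr$priority[i]))
  }
  NA_integer_
}

#' Build the candidate drift-dive table
#'
#' Runs the grouping stage over a summarized-dive table: recovers the
#' selection order of each dive, keeps dives whose order is in the
#' candidate-group whitelist, locates the drifting segment by the group's
#' rules, and computes the signed drift rate over that segment.  Dives
#' with drift rate exactly zero carry sign `"none"` and are excluded from
#' the sign subgroups downstream.
#'
#' @param summaries summarized-dive `data.frame` (selection orders are
#'   recovered with [add_orders()] if the `ifp_order` column is absent).
#' @param rules segment rules table.
#' @param whitelist candidate group labels.
#' @return list with `candidates` — a `data.frame` of dive_id,
#'   start_datetime, group, drift segment, drift_rate, sign, and all shape
#'   variables — and `rejected`, a `data.frame` of dive ids with the
#'   rejection stage (`"order"`, `"degenerate"`, or `"segment"`).
#' @export
build_candidates <- function(summaries, rules = load_segment_rules(),
                             whitelist = drift_groups()) {
  if (!"ifp_order" %in% names(summaries)) summaries <- add_orders(summaries)
  n <- nrow(summaries)
  rows <- vector("list", n)
  rej <- vector("list", n)
  for (i in seq_len(n)) {
    smry <- summaries[i, , drop = FALSE]
    grp <- assign_group(smry$ifp_order, whitelist)
    if (is.na(grp)) {
      rej[[i]] <- data.frame(dive_id = smry$dive_id, stage = "order")
      next
    }
    vars <- compute_shape_variables(smry)
    if (isTRUE(vars$degenerate)) {
      rej[[i]] <- data.frame(dive_id = smry$dive_id, stage = "degenerate")
      next
    }
    seg <- assign_drift_segment(grp, vars, rules)
    if (is.na(seg)) {
      rej[[i]] <- data.frame(dive_id = smry$dive_id, stage = "segment")
      next
    }
    dr <- compute_drift_rate(smry, seg)
    rows[[i]] <- cbind(
      data.frame(dive_id = smry$dive_id,
                 start_datetime = smry$start_datetime,
                 group = grp, drift_segment = as.integer(seg),
                 drift_rate = dr,
                 sign = if (dr < 0) "negative" else if (dr > 0) "positive"
                 else "none",
                 stringsAsFactors = FALSE),
      vars)
  }
  list(candidates = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       rejected = do.call(rbind, rej[!vapply(rej, is.null, logical(1))]))
}
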