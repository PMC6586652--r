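#' Sequential threshold criteria
#'
#' Each candidate drift-dive group carries, separately per drift-rate sign,
#' an ordered list of one-sided or open-interval bounds on single shape
#' variables.  A candidate is accepted when it satisfies every rule
#' matching its (group, sign); the first failing rule rejects it.  All
#' bounds are strict inequalities; bracketed pairs in the source table are
#' open intervals.  Blank cells mean "no rule".
#'
#' The default ruleset ships as a delimited file with columns `group`,
#' `sign` (`neg`/`pos`/`both`), `criterion` (a shape-variable name), `op`
#' (`lt`, `gt` or `between`), `lo`, `hi`, `order_index` and `note`.
#'
#' @param path rules file; defaults to the bundled transcription.
#' @return validated rules `data.frame`.
#' @export
read_threshold_rules <- function(path = system.file("extdata",
                                                    "threshold_rules.csv",
                                                    package = "driftdive")) {
  rules <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("group", "sign", "criterion", "op", "lo", "hi", "order_index")
  miss <- setdiff(need, names(rules))
  if (length(miss))
    stop("threshold rules file missing columns: ",
         paste(miss, collapse = ", "))
  if (!all(rules$op %in% c("lt", "gt", "between")))
    stop("op must be one of lt, gt, between")
  if (!all(rules$sign %in% c("neg", "pos", "both")))
    stop("sign must be one of neg, pos, both")
  bad <- rules$op == "between" & !(rules$lo < rules$hi)
  if (any(bad, na.rm = TRUE))
    stop("interval rules need lo < hi: ",
         paste(rules$criterion[bad], collapse = ", "))
  rules[order(rules$group, rules$sign, rules$order_index), ]
}

.rule_passes <- function(value, op, lo, hi) {
  if (is.na(value)) return(FALSE)
  switch(op,
         lt = value < hi,
         gt = value > lo,
         between = value > lo & value < hi)
}

#' Apply sequential threshold rules to candidate drift dives
#'
#' @param candidates candidate table from [build_candidates()]; must carry
#'   the shape-variable columns, `group` and `sign`.
#' @param rules rules table from [read_threshold_rules()].
#' @return list with `accepted` (subset of `candidates` passing all
#'   matching rules) and `traces`, a per-dive `data.frame` with `outcome`
#'   and, for rejected dives, the failing `criterion` and its
#'   `order_index`.  Candidates with sign `"none"` (drift rate exactly
#'   zero) cannot satisfy sign-specific criteria and are rejected.
#' @export
apply_threshold_rules <- function(candidates, rules = read_threshold_rules()) {
  n <- nrow(candidates)
  outcome <- rep("accepted", n)
  fail_crit <- rep(NA_character_, n)
  fail_idx <- rep(NA_integer_, n)
  sign_code <- c(negative = "neg", positive = "pos", none = "none")
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    if (cand$sign == "none") {
      outcome[i] <- "rejected"
      fail_crit[i] <- "sign"
      next
    }
    rr <- rules[rules$group == cand$group &
                rules$sign %in% c("both", sign_code[[cand$sign]]), ,
                drop = FALSE]
    rr <- rr[order(rr$order_index), , drop = FALSE]
    for (j in seq_len(nrow(rr))) {
      crit <- rr$criterion[j]
      if (!crit %in% names(cand))
        stop("threshold rule references unknown variable '", crit,
             "' (group ", rr$group[j], ")")
      if (!.rule_passes(cand[[crit]], rr$op[j], rr$lo[j], rr$hi[j])) {
        outcome[i] <- "rejected"
        fail_crit[i] <- crit
        fail_idx[i] <- rr$order_index[j]
        break
      }
    }
  }
  traces <- data.frame(dive_id = candidates$dive_id, outcome = outcome,
                       failed_criterion = fail_crit,
                       failed_order_index = fail_idx,
                       stringsAsFactors = FALSE)
  list(accepted = candidates[outcome == "accepted", , drop = FALSE],
       traces = traces)
}

#' Tune a one-sided threshold from labelled dives
#'
#' Scans all cutoffs over the empirical support of one criterion and
#' proposes the one-sided rule that rejects the most non-drift dives
#' subject to losing at most `max_loss` of the true drift dives — the
#' accepting-rejecting analysis used to derive the shipped ruleset
#' (aiming to reject about half the non-drift dives at a cost of 5-10% of
#' the drift dives).
#'
#' @param values numeric criterion values, one per labelled dive.
#' @param labels logical or factor; `TRUE`/`"drift"` marks true drift
#'   dives.
#' @param criterion name for the proposed rule.
#' @param group,sign metadata copied into the proposed rule.
#' @param target_rejection minimum acceptable non-drift rejection fraction.
#' @param max_loss maximum tolerated fraction of drift dives lost.
#' @return list with `rule` (one-row rules `data.frame`, or `NULL` when no
#'   cutoff meets the targets) and `curve`, the accept/reject trade-off:
#'   one row per candidate cutoff and direction with the resulting
#'   `rejection` (of non-drift) and `loss` (of drift).
#' @export
tune_threshold <- function(values, labels, criterion = "x",
                           group = "any", sign = "both",
                           target_rejection = 0.5, max_loss = 0.10) {
  drift <- if (is.logical(labels)) labels else labels %in% c("drift", "TRUE")
  if (!any(drift) || all(drift))
    stop("need both drift and non-drift dives to tune a threshold")
  if (length(unique(values)) == 1L)
    return(list(rule = NULL, curve = NULL,
                diagnostic = "criterion is constant; no threshold exists"))
  cuts <- sort(unique(values))
  eps <- 1e-9 * max(1, diff(range(values)))
  grid <- rbind(
    data.frame(op = "lt", cut = cuts + eps),   # keep value < cut
    data.frame(op = "gt", cut = cuts - eps))   # keep value > cut
  keep <- function(op, cut) if (op == "lt") values < cut else values > cut
  curve <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    k <- keep(grid$op[i], grid$cut[i])
    data.frame(op = grid$op[i], cut = grid$cut[i],
               rejection = mean(!k[!drift]),
               loss = mean(!k[drift]))
  }))
  ok <- curve$loss <= max_loss & curve$rejection >= target_rejection
  if (!any(ok)) return(list(rule = NULL, curve = curve))
  cand <- curve[ok, ]
  cand <- cand[order(-cand$rejection, cand$loss), ]  # ties: least drift loss
  best <- cand[1L, ]
  rule <- data.frame(group = group, sign = sign, criterion = criterion,
                     op = best$op,
                     lo = if (best$op == "gt") best$cut else NA_real_,
                     hi = if (best$op == "lt") best$cut else NA_real_,
                     order_index = 1L,
                     note = "tuned from labelled data",
                     stringsAsFactors = FALSE)
  list(rule = rule, curve = curve)
}
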