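mk_candidate <- function(group = "2.1.3.4", sign = "negative", ...) {
  v <- list(...)
  base <- data.frame(dive_id = "c1", group = group, sign = sign,
                     drift_rate = if (sign == "negative") -0.2 else 0.2,
                     stringsAsFactors = FALSE)
  for (nm in names(v)) base[[nm]] <- v[[nm]]
  base
}

test_that("the first failing rule rejects and is named in the trace", {
  rules <- data.frame(group = "2.1.3.4", sign = "neg", criterion = "d1",
                      op = "lt", lo = NA_real_, hi = 0.8, order_index = 1L)
  out <- apply_threshold_rules(mk_candidate(d1 = 0.9), rules)
  expect_equal(nrow(out$accepted), 0L)
  expect_equal(out$traces$failed_criterion, "d1")
  out2 <- apply_threshold_rules(mk_candidate(d1 = 0.7), rules)
  expect_equal(nrow(out2$accepted), 1L)
  expect_true(is.na(out2$traces$failed_criterion))
})

test_that("the bundled ruleset carries the published anchor cells", {
  rules <- read_threshold_rules()
  # d1 < 0.8 for negative dives of group 2.1.3.4
  expect_true(any(rules$group == "2.1.3.4" & rules$sign == "neg" &
                  rules$criterion == "d1" & rules$op == "lt" &
                  rules$hi == 0.8))
  # group 3.2.1.4 takes the 0.8 bound on d2 instead of d1
  r3214 <- rules[rules$group == "3.2.1.4", ]
  expect_false(any(r3214$criterion == "d1"))
  expect_true(any(r3214$criterion == "d2" & r3214$op == "lt" &
                  r3214$hi == 0.8))
  # bracketed cells are open intervals with lo < hi
  iv <- rules[rules$op == "between", ]
  expect_true(all(iv$lo < iv$hi))
})

test_that("an empty ruleset accepts every signed candidate", {
  empty <- read_threshold_rules()[0, ]
  cands <- rbind(mk_candidate(d1 = 0.99),
                 mk_candidate(sign = "positive", d1 = 0.5))
  out <- apply_threshold_rules(cands, empty)
  expect_equal(nrow(out$accepted), 2L)
})

test_that("accepted membership ignores rule order; traces reflect it", {
  rules <- data.frame(group = "2.1.3.4", sign = "neg",
                      criterion = c("d1", "t1"), op = "lt",
                      lo = NA_real_, hi = c(0.8, 0.14),
                      order_index = c(1L, 2L))
  cand <- mk_candidate(d1 = 0.9, t1 = 0.5)  # fails both
  a <- apply_threshold_rules(cand, rules)
  rules2 <- rules
  rules2$order_index <- c(2L, 1L)
  b <- apply_threshold_rules(cand, rules2)
  expect_equal(nrow(a$accepted), nrow(b$accepted))
  expect_equal(a$traces$failed_criterion, "d1")
  expect_equal(b$traces$failed_criterion, "t1")
})

test_that("tightening a one-sided bound never grows the accepted set", {
  set.seed(3)
  cands <- do.call(rbind, lapply(1:40, function(i)
    mk_candidate(d1 = runif(1))))
  cands$dive_id <- paste0("c", 1:40)
  rule <- function(hi) data.frame(group = "2.1.3.4", sign = "neg",
                                  criterion = "d1", op = "lt",
                                  lo = NA_real_, hi = hi, order_index = 1L)
  loose <- apply_threshold_rules(cands, rule(0.8))$accepted$dive_id
  tight <- apply_threshold_rules(cands, rule(0.6))$accepted$dive_id
  expect_true(all(tight %in% loose))
})

test_that("a rule naming an unknown variable is a configuration error", {
  rules <- data.frame(group = "2.1.3.4", sign = "neg",
                      criterion = "nope", op = "lt", lo = NA_real_,
                      hi = 1, order_index = 1L)
  expect_error(apply_threshold_rules(mk_candidate(d1 = 0.5), rules),
               "unknown variable 'nope'")
})

test_that("threshold tuning finds the separating cutoff", {
  # perfectly separable
  set.seed(14)
  vals <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  is_drift <- rep(c(TRUE, FALSE), each = 50)
  sep <- tune_threshold(vals, is_drift, criterion = "x")
  expect_equal(sep$rule$op, "lt")
  expect_true(all(vals[is_drift] < sep$rule$hi))   # keeps every drift dive
  expect_true(all(vals[!is_drift] >= sep$rule$hi)) # rejects every non-drift
  best <- sep$curve[sep$curve$op == "lt" &
                    abs(sep$curve$cut - sep$rule$hi) < 1e-9, ]
  expect_equal(best$rejection, 1)
  expect_equal(best$loss, 0)

  # identical distributions: nothing to find
  x <- runif(80)
  none <- tune_threshold(c(x, x), rep(c(TRUE, FALSE), each = 80))
  expect_null(none$rule)

  # quantile arithmetic fixes the optimum: drift below 0.5, non-drift
  # uniform on (0, 1) -> cutoff ~0.5 rejecting ~50%
  set.seed(21)
  v <- c(runif(400, 0, 0.5), runif(400, 0, 1))
  lab <- rep(c(TRUE, FALSE), each = 400)
  mid <- tune_threshold(v, lab, target_rejection = 0.45, max_loss = 0.05)
  expect_equal(mid$rule$op, "lt")
  # the loss budget places the cutoff at the drift quantile just below 0.5
  expect_lt(abs(mid$rule$hi - 0.5), 0.06)
  rej <- mid$curve$rejection[mid$curve$op == "lt" &
                             abs(mid$curve$cut - mid$rule$hi) < 1e-9]
  expect_lt(abs(rej - 0.5), 0.08)

  # constant criterion yields a diagnostic, not a rule
  const <- tune_threshold(rep(1, 40), rep(c(TRUE, FALSE), 20))
  expect_null(const$rule)
  expect_match(const$diagnostic, "constant")
})
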