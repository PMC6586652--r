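mk_summary <- function(times = c(150, 750, 830, 900),
                       depths = c(250, 340, 220, 100), E = 1000,
                       res = c(300, 150, 30, 5), id = "s") {
  summarized_dive(id, times, depths, E, residuals = res)
}

test_that("shape variables follow their definitions", {
  s <- mk_summary(times = c(100, 400, 700, 900),
                  depths = c(200, 250, 300, 400), E = 1000)
  v <- compute_shape_variables(s)
  expect_equal(c(v$d1, v$d2, v$d3, v$d4), c(0.5, 0.625, 0.75, 1.0))
  expect_equal(v$meand, 0.71875)
  expect_equal(v$mdepthbias, 900 - 500)        # deepest point at T4
  expect_equal(v$ps0, 0.1)
  expect_equal(v$f, 50 / 300)
  expect_equal(v$sratio, (200 / 100) / (50 / 300))
  expect_equal(v$mrratio, 5 / 400)
  s2 <- mk_summary(times = c(100, 400, 700, 900),
                   depths = c(400, 300, 250, 200), E = 1000)
  expect_equal(compute_shape_variables(s2)$mdepthbias, 100 - 500)
})

test_that("collinear inflection points have zero regression residuals", {
  s <- mk_summary(times = c(100, 300, 500, 700),
                  depths = c(100, 200, 300, 400), E = 1000)
  v <- compute_shape_variables(s)
  expect_equal(c(v$r1, v$r2, v$r3, v$r4), rep(0, 4), tolerance = 1e-9)
  expect_equal(v$sdd, sd(c(100, 200, 300, 400) / 400))
})

test_that("proportional identities hold on random summaries", {
  set.seed(5)
  for (i in 1:30) {
    tt <- sort(runif(4, 50, 950))
    dd <- runif(4, 50, 600)
    s <- mk_summary(times = tt, depths = dd, E = 1000,
                    res = sort(runif(4, 0, 100), decreasing = TRUE))
    v <- compute_shape_variables(s)
    expect_equal(v$ps0 + v$ps1 + v$ps2 + v$ps3 + v$ps4, 1, tolerance = 1e-9)
    expect_equal(v$r1 + v$r2 + v$r3 + v$r4, 0, tolerance = 1e-7)
    expect_true(all(c(v$d1, v$d2, v$d3, v$d4) <= 1))
    expect_true(v$t1 < v$t2 && v$t2 < v$t3 && v$t3 < v$t4 && v$t4 < 1)
  }
})

test_that("proportional variables are scale invariant; rates scale as c/k", {
  set.seed(9)
  tt <- sort(runif(4, 50, 950)); dd <- runif(4, 50, 600)
  res <- sort(runif(4, 0, 80), decreasing = TRUE)
  s1 <- mk_summary(times = tt, depths = dd, E = 1000, res = res)
  ck <- c(c = 2.7, k = 0.4)
  s2 <- mk_summary(times = tt * ck["k"], depths = dd * ck["c"],
                   E = 1000 * ck["k"], res = res * ck["c"])
  v1 <- compute_shape_variables(s1)
  v2 <- compute_shape_variables(s2)
  for (nm in c("d1", "d2", "d3", "d4", "t1", "t2", "t3", "t4",
               "ps0", "ps1", "ps2", "ps3", "ps4", "meand", "sdd",
               "mdepthr", "mrratio", "sratio", "avratio"))
    expect_equal(v2[[nm]], v1[[nm]], tolerance = 1e-9, label = nm)
  for (seg in 1:3)
    expect_equal(compute_drift_rate(s2, seg),
                 compute_drift_rate(s1, seg) * ck[["c"]] / ck[["k"]])
})

test_that("drift rate is signed depth change over time, sinking negative", {
  s <- summarized_dive("r", times = c(300, 900, 950, 980),
                       depths = c(200, 320, 150, 60), E = 1000)
  expect_equal(compute_drift_rate(s, 1), -0.2)
  s2 <- summarized_dive("r2", times = c(300, 900, 950, 980),
                        depths = c(320, 200, 150, 60), E = 1000)
  expect_equal(compute_drift_rate(s2, 1), +0.2)
  expect_error(compute_drift_rate(s, 4), "must be 1, 2 or 3")
})

test_that("exactly the eight whitelisted orders are accepted", {
  expect_equal(assign_group("3.2.1.4"), "3.2.1.4")
  expect_equal(assign_group("4.2.1.3"), "4.2.1.3")
  expect_true(is.na(assign_group("1.2.3.4")))
})

test_that("segment rules follow the published per-group logic", {
  rules <- load_segment_rules()
  rnd_vars <- function(over = list()) {
    s <- mk_summary(times = sort(runif(4, 50, 950)),
                    depths = runif(4, 50, 600), E = 1000)
    v <- compute_shape_variables(s)
    for (nm in names(over)) v[[nm]] <- over[[nm]]
    v
  }
  set.seed(77)
  for (i in 1:20) {
    # group 3.2.1.4: always segment 2
    expect_equal(as.integer(assign_drift_segment("3.2.1.4", rnd_vars(), rules)), 2L)
    # group 2.1.4.3: long first segment means it is the drift segment
    expect_equal(as.integer(assign_drift_segment("2.1.4.3",
      rnd_vars(list(ps1 = 0.30)), rules)), 1L)
    # group 2.1.3.4: side of mid-dive on which the deepest point falls
    expect_equal(as.integer(assign_drift_segment("2.1.3.4",
      rnd_vars(list(mdepthbias = 50)), rules)), 1L)
    expect_equal(as.integer(assign_drift_segment("2.1.3.4",
      rnd_vars(list(mdepthbias = -50)), rules)), 2L)
  }
  # degenerate variables reject the dive
  v <- rnd_vars(); v$degenerate <- TRUE
  expect_true(is.na(assign_drift_segment("3.2.1.4", v, rules)))
})

test_that("zero drift rate is excluded from the sign subgroups", {
  s <- summarized_dive("z", times = c(100, 180, 700, 920),
                       depths = c(280, 300, 300, 60), E = 1000,
                       residuals = c(250, 90, 20, 4), order = "3.2.1.4")
  s$ifp_order <- "3.2.1.4"
  s$res_last <- 4
  cand <- build_candidates(s)
  expect_equal(cand$candidates$sign, "none")
  out <- apply_threshold_rules(cand$candidates)
  expect_equal(nrow(out$accepted), 0L)
  expect_equal(out$traces$failed_criterion, "sign")
})
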