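# Shared fixtures and independent oracles, built in code at test time.

# deterministic symmetric V dive: linear down, linear up
make_vee <- function(depth = 300, rate = 2, dt = 30) {
  half <- seq(0, depth, by = rate * dt)
  depths <- c(half, rev(half)[-1])
  high_res_profile("vee", times = seq_along(depths) * dt - dt, depths = depths)
}

# random wiggly dive profile for oracle comparisons (n <= 50 samples)
make_random_profile <- function(n, id = "rnd") {
  tt <- seq(0, by = 30, length.out = n)
  apex <- runif(1, 120, 500)
  base <- approx(c(0, n %/% 2, n - 1), c(0, apex, 0), xout = 0:(n - 1))$y
  dd <- pmax(base + c(0, rnorm(n - 2, 0, runif(1, 1, 25)), 0), 0)
  dd[c(1, n)] <- 0
  high_res_profile(id, tt, dd)
}

# independent brute-force broken-stick oracle: explicit O(n^2) scans and a
# hand-rolled interpolation loop (no approx(), no shared code path)
brute_interp <- function(xs, ys, x) {
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    j <- max(which(xs <= x[i]))
    if (xs[j] == x[i]) out[i] <- ys[j]
    else {
      w <- (x[i] - xs[j]) / (xs[j + 1] - xs[j])
      out[i] <- (1 - w) * ys[j] + w * ys[j + 1]
    }
  }
  out
}

brute_bsa <- function(profile, n_pts = 4) {
  tt <- profile$times
  dd <- profile$depths
  n <- length(tt)
  sel <- integer(0)
  res <- numeric(0)
  for (k in seq_len(n_pts)) {
    cand <- setdiff(2:(n - 1), sel)
    if (k == 1) {
      best <- cand[which.max(dd[cand])]
      nodes <- c(1, n)
      disc <- abs(dd[best] - brute_interp(tt[nodes], dd[nodes], tt[best]))
    } else {
      nodes <- c(1, n, sel)
      best <- cand[1]; disc <- -1
      for (i in cand) {
        d <- abs(dd[i] - brute_interp(tt[nodes], dd[nodes], tt[i]))
        if (d > disc + 1e-12) { disc <- d; best <- i }
      }
    }
    sel <- c(sel, best)
    res <- c(res, disc)
  }
  list(indices = sel, residuals = res,
       order = match(sel, sort(sel)))
}

# small labelled trip shared by several files (built once per test run)
small_trip <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_trip(trip_config(n_days = 8, dives_per_day = 40,
                                          seed = 42))
    cache
  }
})

# closed-form posterior inclusion probability for a two-component normal
# mixture with known parameters (oracle for the trajectory filter)
mixture_p_in <- function(r, mu, sd_in, sd_out, p) {
  a <- p * dnorm(r, mu, sd_in)
  b <- (1 - p) * dnorm(r, mu, sd_out)
  a / (a + b)
}
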