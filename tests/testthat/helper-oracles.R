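# Independent oracles and fixture builders used across the suite.
# These deliberately use the slowest, most literal formulation of each rule
# so they stay independent of the package's vectorized implementations.

# Brute-force sliding-window labeller: direct enumeration of all windows.
oracle_label_points <- function(t, x, theta, tau) {
  n <- length(t)
  lab <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    j <- NA_integer_
    for (jj in i:n) {
      if (t[jj] - t[i] >= tau) { j <- jj; break }
    }
    if (!is.na(j)) {
      d <- x[j] - x[i]
      lab[i] <- if (d >= theta) "A" else if (d <= -theta) "R" else "S"
    }
  }
  if (all(is.na(lab))) {
    net <- x[n] - x[1]
    lab[] <- if (net >= theta) "A" else if (net <= -theta) "R" else "S"
  } else {
    for (i in seq_len(n)) if (is.na(lab[i])) lab[i] <- lab[i - 1L]
  }
  lab
}

# Brute-force two-sample KS distance: evaluate both ECDFs at every pooled
# observation.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  Fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(Fa - Fb))
}

# Random short track for property tests: mixes smooth drift, jumps and
# occasional frame gaps.
random_track <- function(n_max = 50L) {
  n <- sample(1:n_max, 1L)
  frames <- sort(sample(0:(n_max * 2L), n))
  t <- frames * 0.156
  v <- stats::rnorm(1L, 0, 2)
  x <- cumsum(c(stats::runif(1L, 0, 50),
                v * diff(t) + stats::rnorm(n - 1L, 0, 0.3)))
  list(t = t, x = x)
}

# Unique track key (track ids repeat across kymographs).
track_key <- function(df) paste(df$kymograph_id, df$track_id, sep = "\r")

# Calibrated-track data.frame from plain vectors.
make_tracks_df <- function(..., condition = "cond") {
  specs <- list(...)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(condition = condition,
               kymograph_id = if (!is.null(s$kymo)) s$kymo else "K1",
               track_id = if (!is.null(s$id)) s$id else sprintf("T%02d", i),
               axon_distance_um = if (!is.null(s$dist)) s$dist else NA_real_,
               t_s = s$t, x_um = s$x, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Noise-free piecewise-constant-velocity track sampled at the standard
# frame interval: phases is a list of c(v, duration_s).
piecewise_track <- function(phases, x0 = 10, dt = 0.156) {
  t_total <- sum(vapply(phases, `[[`, numeric(1), 2))
  t <- seq(0, t_total, by = dt)
  x <- numeric(length(t))
  for (i in seq_along(t)) {
    rem <- t[i]; xx <- x0
    for (p in phases) {
      step <- min(rem, p[2])
      xx <- xx + p[1] * step
      rem <- rem - step
      if (rem <= 0) break
    }
    x[i] <- xx
  }
  list(t = t, x = x)
}
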