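# Independent oracles used across the suite.  These deliberately use the
# slowest, most literal formulation of each quantity.

# TA-MSD by an explicit double loop over all ordered point pairs.
tamsd_oracle <- function(track) {
  n <- nrow(track)
  dt <- median(diff(track$t_s) / diff(track$frame))
  acc <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- track$frame[j] - track$frame[i]
    d2 <- (track$x_um[j] - track$x_um[i])^2 +
      (track$y_um[j] - track$y_um[i])^2
    key <- as.character(k)
    acc[[key]] <- c(acc[[key]], d2)
  }
  ks <- sort(as.integer(names(acc)))
  data.frame(tau_s = ks * dt,
             msd_um2 = vapply(as.character(ks),
                              function(k) mean(acc[[k]]), numeric(1)),
             n_pairs = vapply(as.character(ks),
                              function(k) length(acc[[k]]), integer(1)),
             row.names = NULL)
}

# Exhaustive gated assignment: enumerate every injective partial matching
# between rows (set A) and columns (set B) of the squared-distance matrix,
# maximizing sum(gate^2 - d^2) over matched pairs (the LAP-with-rejection
# objective).  Returns, for each row, the matched column or NA.
bf_match <- function(d2, gate) {
  na <- nrow(d2); nb <- ncol(d2)
  gate2 <- gate^2
  best_w <- 0
  best_m <- rep(NA_integer_, na)
  rec <- function(i, used, w, m) {
    if (i > na) {
      if (w > best_w + 1e-12) {
        best_w <<- w
        best_m <<- m
      }
      return()
    }
    rec(i + 1L, used, w, m)
    for (j in seq_len(nb)) {
      if (!used[j] && d2[i, j] < gate2) {
        m[i] <- j
        used[j] <- TRUE
        rec(i + 1L, used, w + gate2 - d2[i, j], m)
        used[j] <- FALSE
        m[i] <- NA_integer_
      }
    }
  }
  rec(1L, logical(nb), 0, best_m)
  best_m
}

# random gapped track: Brownian positions, a random subset of frames kept
random_gapped_track <- function(n_frames = 30, keep_frac = 0.7,
                                dt = 0.017, D = 0.1) {
  f <- sort(sample(0:(n_frames - 1), max(3, round(keep_frac * n_frames))))
  data.frame(frame = f, t_s = f * dt,
             x_um = cumsum(rnorm(length(f), sd = sqrt(2 * D * dt))),
             y_um = cumsum(rnorm(length(f), sd = sqrt(2 * D * dt))))
}

# match detections to truth positions within a radius; returns the number
# of truth spots recovered and the number of unmatched detections
match_to_truth <- function(det_x, det_y, tru_x, tru_y, radius) {
  n_hit <- 0L
  used <- logical(length(det_x))
  for (s in seq_along(tru_x)) {
    d <- sqrt((det_x - tru_x[s])^2 + (det_y - tru_y[s])^2)
    d[used] <- Inf
    if (length(d) && min(d) <= radius) {
      n_hit <- n_hit + 1L
      used[which.min(d)] <- TRUE
    }
  }
  list(n_hit = n_hit, n_false = sum(!used))
}

# noiseless curve from the power-law model MSD = 2 d D tau^alpha
powerlaw_curve <- function(D, alpha, dt = 0.017, n = 11, d = 2) {
  tau <- (1:n) * dt
  structure(data.frame(tau_s = tau, msd_um2 = 2 * d * D * tau^alpha,
                       n_pairs = 100L),
            class = c("msd_curve", "data.frame"), frame_interval = dt)
}
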