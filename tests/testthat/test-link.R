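dt <- 0.017

make_locs <- function(frame, x, y) {
  structure(data.frame(frame = frame, x_um = x, y_um = y,
                       quality = rep(1, length(frame)),
                       intensity = rep(1, length(frame))),
            class = c("spt_localizations", "data.frame"),
            frame_interval = dt)
}

test_that("two well-separated static spots give two clean tracks", {
  locs <- make_locs(rep(0:9, each = 2),
                    rep(c(1, 5), 10), rep(c(1, 5), 10))
  tracks <- link_frames(locs, link_config())
  expect_equal(length(unique(tracks$track_id)), 2)
  expect_true(all(table(tracks$track_id) == 10))
  # no identity switches: each track stays at its spot
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    expect_equal(length(unique(tr$x_um)), 1)
  }
})

test_that("a single missed frame is bridged by gap closing", {
  f <- setdiff(0:9, 5L)
  locs <- make_locs(f, rep(2, 9), rep(2, 9))
  tracks <- link_frames(locs, link_config(max_frame_gap = 2))
  expect_equal(length(unique(tracks$track_id)), 1)
  expect_equal(nrow(tracks), 9)
  expect_equal(sort(tracks$frame), f)

  # with gap closing disabled the track splits in two
  t2 <- link_frames(locs, link_config(max_frame_gap = 0))
  expect_equal(length(unique(t2$track_id)), 2)
})

test_that("empty input and malformed configs are handled", {
  empty <- make_locs(integer(), numeric(), numeric())
  tracks <- link_frames(empty, link_config())
  expect_s3_class(tracks, "spt_tracks")
  expect_equal(nrow(tracks), 0)
  expect_error(link_config(max_link_distance_um = 0), "max_link_distance")
  expect_error(link_config(min_spots = 1), "min_spots")
})

test_that("with a single particle per frame and a wide gate linking gives
           the trivial chain", {
  set.seed(2)
  n <- 25
  locs <- make_locs(0:(n - 1), cumsum(rnorm(n)), cumsum(rnorm(n)))
  tracks <- link_frames(locs, link_config(max_link_distance_um = 1e6))
  expect_equal(length(unique(tracks$track_id)), 1)
  expect_equal(tracks$x_um, locs$x_um)
})

test_that("frame-to-frame assignment agrees exactly with the brute-force
           oracle on random instances", {
  set.seed(99)
  for (rep in 1:60) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    ax <- runif(na, 0, 3); ay <- runif(na, 0, 3)
    bx <- runif(nb, 0, 3); by <- runif(nb, 0, 3)
    gate <- runif(1, 0.5, 2)
    d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
    expect_identical(sptmsd:::lap_match(ax, ay, bx, by, gate),
                     bf_match(d2, gate))
  }
})

test_that("multi-frame linking reproduces the chained brute-force
           partition", {
  set.seed(123)
  for (rep in 1:20) {
    n_frames <- 6; n_per <- 5
    frames <- rep(0:(n_frames - 1), each = n_per)
    x <- runif(n_frames * n_per, 0, 4)
    y <- runif(n_frames * n_per, 0, 4)
    gate <- 0.8
    locs <- make_locs(frames, x, y)
    tracks <- link_frames(locs,
                          link_config(max_link_distance_um = gate,
                                      max_frame_gap = 0))
    # oracle: chain per-pair brute-force matchings
    nxt <- rep(NA_integer_, nrow(locs))
    for (f in 0:(n_frames - 2)) {
      a <- which(locs$frame == f); b <- which(locs$frame == f + 1)
      d2 <- outer(x[a], x[b], "-")^2 + outer(y[a], y[b], "-")^2
      m <- bf_match(d2, gate)
      nxt[a[!is.na(m)]] <- b[m[!is.na(m)]]
    }
    # compare partitions as sets of point chains
    chains <- function(nx) {
      heads <- setdiff(seq_along(nx), nx[!is.na(nx)])
      sort(vapply(heads, function(h) {
        ch <- h
        while (!is.na(nx[ch[length(ch)]])) ch <- c(ch, nx[ch[length(ch)]])
        paste(ch, collapse = "-")
      }, character(1)))
    }
    got <- lapply(split(tracks, tracks$track_id), function(tr)
      paste(match(paste(tr$frame, tr$x_um), paste(locs$frame, locs$x_um)),
            collapse = "-"))
    expect_setequal(unlist(got), chains(nxt))
  }
})

test_that("no detection is used twice and linked detections are a subset
           of the input", {
  set.seed(7)
  locs <- make_locs(rep(0:9, each = 4),
                    runif(40, 0, 2), runif(40, 0, 2))
  tracks <- link_frames(locs, link_config(max_link_distance_um = 0.6))
  key_in <- paste(locs$frame, locs$x_um, locs$y_um)
  key_out <- paste(tracks$frame, tracks$x_um, tracks$y_um)
  expect_true(all(key_out %in% key_in))
  expect_false(any(duplicated(key_out)))
})

test_that("filter_tracks keeps only tracks with enough localized points", {
  locs <- make_locs(c(0:2, 0:9, 0:4 * 2),
                    c(rep(1, 3), rep(5, 10), rep(9, 5)),
                    c(rep(1, 3), rep(5, 10), rep(9, 5)))
  locs <- locs[order(locs$frame), ]
  tracks <- link_frames(locs, link_config(max_frame_gap = 2))
  expect_equal(length(unique(tracks$track_id)), 3)
  kept <- filter_tracks(tracks, min_spots = 5)
  expect_equal(length(unique(kept$track_id)), 2)
  expect_true(all(table(kept$track_id) >= 5))
  # identity on track lists already above the threshold
  expect_equal(as.data.frame(filter_tracks(kept, 2)), as.data.frame(kept))
  expect_error(filter_tracks(tracks, 1), "min_spots")
})

test_that("linking a simulated cohort recovers the true frame-to-frame
           links", {
  gt <- simulate_cohort(list(list(model = brownian_model(0.08), n = 12)),
                        n_steps = 40, dt = dt, seed = 21,
                        field_um = c(20, 20))
  locs <- make_locs(gt$frame, gt$x_um, gt$y_um)
  locs <- locs[order(locs$frame), ]
  tracks <- filter_tracks(link_frames(locs, link_config()), 10)
  # every reconstructed track is one truth track: compare link sets
  true_links <- with(gt, paste(track_id, frame))
  n_true <- sum(duplicated(gt$track_id))          # links = points - tracks
  link_key <- function(tr) {
    unlist(lapply(split(tr, tr$track_id), function(d) {
      if (nrow(d) < 2) return(character(0))
      paste(d$x_um[-nrow(d)], d$y_um[-nrow(d)],
            d$x_um[-1], d$y_um[-1])
    }))
  }
  got <- link_key(tracks)
  want <- link_key(gt)
  expect_gte(length(intersect(got, want)) / n_true, 0.99)
})
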