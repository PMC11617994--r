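dt <- 0.017

test_that("degenerate models produce exact trajectories", {
  # zero-variance Brownian: all positions identical
  tr <- simulate_track(brownian_model(0), n_steps = 20, dt = dt, seed = 4)
  expect_true(all(tr$x_um == tr$x_um[1]) && all(tr$y_um == tr$y_um[1]))

  # pure drift: x advances by v * dt along the heading
  tr <- simulate_track(directed_model(D = 0, v = 1, heading = 0),
                       n_steps = 3, dt = 0.017, seed = 1)
  expect_equal(tr$x_um, c(0, 0.017, 0.034))
  expect_equal(tr$y_um, c(0, 0, 0))
})

test_that("malformed models and arguments are rejected with field names", {
  expect_error(brownian_model(-1), "D")
  expect_error(anomalous_model(0.1, alpha = 2.5), "alpha")
  expect_error(confined_model(0.1, R_c = 0), "R_c")
  expect_error(directed_model(0.1, v = -2), "v")
  expect_error(simulate_track(brownian_model(0.1), 10, dt = -1, seed = 1),
               "dt")
  expect_error(simulate_track(brownian_model(0.1), 1, dt = dt, seed = 1),
               "n_steps")
  expect_error(simulate_cohort(list(), 10, dt, seed = 1), "empty")
})

test_that("Brownian ensemble MSD matches 4 D tau over the first 10 delays", {
  D <- 0.1
  gt <- simulate_cohort(list(list(model = brownian_model(D), n = 400)),
                        n_steps = 100, dt = dt, seed = 42)
  curves <- lapply(split_tracks(gt), tamsd, max_lag_frames = 10)
  ens <- ensemble_msd(curves, weighting = "uniform")
  expected <- 4 * D * ens$tau_s
  # each delay within 3 standard errors of the closed form
  expect_true(all(abs(ens$msd_um2 - expected) <= 3 * ens$sem))
})

test_that("fBm ensemble MSD matches the closed form 4 D tau^alpha", {
  D <- 0.05; alpha <- 0.5
  m <- anomalous_model(D, alpha)
  v <- vapply(1:2000, function(i) {
    tr <- simulate_track(m, 2, dt, seed = i)
    (tr$x_um[2] - tr$x_um[1])^2 + (tr$y_um[2] - tr$y_um[1])^2
  }, numeric(1))
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 4 * D * dt^alpha), 2 * se)
})

test_that("fBm tracks refit by the MSD module recover alpha within 0.05", {
  for (alpha in c(0.4, 0.7, 1.0)) {
    m <- anomalous_model(0.05, alpha)
    al <- vapply(1:80, function(i) {
      tr <- simulate_track(m, 500, dt, seed = 9000 + i)
      fit_powerlaw(tamsd(tr, max_lag_frames = 12))$alpha
    }, numeric(1))
    expect_lt(abs(mean(al) - alpha), 0.05)
  }
})

test_that("confined ensemble MSD plateaus at R_c^2", {
  R_c <- 0.25; D <- 0.1
  gt <- simulate_cohort(list(list(model = confined_model(D, R_c), n = 150)),
                        n_steps = 200, dt = dt, seed = 7)
  ens <- ensemble_msd(lapply(split_tracks(gt), tamsd))
  # tau >> R_c^2 / (4 D) = 0.156 s
  late <- ens$msd_um2[ens$tau_s >= 1 & ens$tau_s <= 2]
  expect_lt(abs(mean(late) - R_c^2) / R_c^2, 0.1)
})

test_that("directed ensemble MSD matches 4 D tau + v^2 tau^2", {
  D <- 0.05; v <- 1
  gt <- simulate_cohort(list(list(model = directed_model(D, v, 0.7),
                                  n = 300)),
                        n_steps = 60, dt = dt, seed = 11)
  ens <- ensemble_msd(lapply(split_tracks(gt), tamsd), "uniform")
  sel <- ens$tau_s <= 30 * dt
  expected <- 4 * D * ens$tau_s + v^2 * ens$tau_s^2
  expect_true(all(abs(ens$msd_um2[sel] - expected[sel]) <=
                    3 * ens$sem[sel]))
})

test_that("cohorts are reproducible and stable under composition growth", {
  spec1 <- list(list(model = brownian_model(0.1), n = 5))
  g1 <- simulate_cohort(spec1, 50, dt, seed = 3)
  g2 <- simulate_cohort(spec1, 50, dt, seed = 3)
  expect_identical(g1, g2)

  # appending a second model leaves the first five tracks untouched
  spec2 <- list(list(model = brownian_model(0.1), n = 5),
                list(model = directed_model(0.05, 1), n = 3))
  g3 <- simulate_cohort(spec2, 50, dt, seed = 3)
  expect_equal(length(unique(g3$track_id)), 8)
  expect_equal(as.data.frame(g3[g3$track_id <= 5, ]),
               as.data.frame(g1), ignore_attr = TRUE)
  expect_setequal(unique(g3$model), c("brownian", "directed"))
})

test_that("rendering: empty truth gives pure background at the right mean", {
  acq <- acquisition_config(n_frames = 30, field_px = c(40, 40),
                            background = 50)
  empty <- simulate_cohort(list(list(model = brownian_model(0.1), n = 1)),
                           2, dt, seed = 1)[0, ]
  mv <- render_movie(empty, acq, seed = 1)
  expect_equal(mean(mv$frames), 50, tolerance = 0.02)
  mv0 <- render_movie(empty, acq, noise = FALSE)
  expect_true(all(mv0$frames == 50))
})

test_that("a noiseless static spot renders at its true position", {
  acq <- acquisition_config(n_frames = 2, field_px = c(31, 31),
                            background = 10)
  px <- acq$pixel_size_nm / 1000
  # truth at pixel (14, 17) center plus a small subpixel offset
  tru <- data.frame(track_id = 1L, frame = 0L, t_s = 0,
                    x_um = (17 + 0.5 + 0.3) * px,
                    y_um = (14 + 0.5 - 0.2) * px, model = "brownian")
  mv <- render_movie(tru, acq, noise = FALSE)
  fr <- mv$frames[1, , ]
  am <- which(fr == max(fr), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(14, 17) + 1L)  # nearest pixel (1-based)
  w <- fr - 10
  cx <- sum(t(w) * (col(fr)[1, ] - 1)) / sum(w)  # 0-based column centroid
  cy <- sum(w * (row(fr)[, 1] - 1)) / sum(w)
  expect_lt(abs(cx - (17 + 0.3)), 0.05)
  expect_lt(abs(cy - (14 - 0.2)), 0.05)
})

test_that("identical seeds give identical movies; rendering is gated on
           sensible configs", {
  gt <- simulate_cohort(list(list(model = brownian_model(0.05), n = 3)),
                        10, dt, seed = 2, field_um = c(2.6, 2.6))
  acq <- acquisition_config(n_frames = 10, field_px = c(40, 40))
  m1 <- render_movie(gt, acq, seed = 5)
  m2 <- render_movie(gt, acq, seed = 5)
  expect_identical(m1$frames, m2$frames)
  expect_error(acquisition_config(field_px = c(0, 10)))
  expect_error(acquisition_config(photons_per_spot = -5))
})
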