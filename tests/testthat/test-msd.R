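dt <- 0.017

test_that("tamsd reproduces hand-computed values", {
  # static track: zero MSD at the single delay
  tr <- data.frame(frame = 0:1, t_s = c(0, 1), x_um = c(2, 2),
                   y_um = c(3, 3))
  expect_equal(tamsd(tr)$msd_um2, 0)

  # 1D embedding x = (0, 1, 2) um at 1 s spacing
  tr <- data.frame(frame = 0:2, t_s = 0:2, x_um = c(0, 1, 2), y_um = 0)
  curve <- tamsd(tr)
  expect_equal(curve$tau_s, c(1, 2))
  expect_equal(curve$msd_um2, c(1, 4))
  expect_equal(curve$n_pairs, c(2L, 1L))

  expect_error(tamsd(tr[1, ]), "2 points")
})

test_that("tamsd equals the brute-force pairwise oracle on gapped tracks", {
  set.seed(31)
  for (i in 1:25) {
    tr <- random_gapped_track()
    got <- tamsd(tr)
    want <- tamsd_oracle(tr)
    expect_equal(got$tau_s, want$tau_s)
    expect_equal(got$msd_um2, want$msd_um2)
    expect_equal(got$n_pairs, want$n_pairs)
  }
})

test_that("ensemble averaging is correct for hand-computable cases", {
  c1 <- powerlaw_curve(0.1, 1)
  # identical curves: ensemble equals each input with zero SEM
  ens <- ensemble_msd(list(c1, c1, c1))
  expect_equal(ens$msd_um2, c1$msd_um2)
  expect_true(all(ens$sem == 0))

  # single curve: identity
  e1 <- ensemble_msd(list(c1))
  expect_equal(e1$msd_um2, c1$msd_um2)

  # uniform weighting: plain mean
  ca <- powerlaw_curve(0.1, 1, n = 1); ca$msd_um2 <- 1; ca$n_pairs <- 1L
  cb <- powerlaw_curve(0.1, 1, n = 1); cb$msd_um2 <- 3; cb$n_pairs <- 3L
  expect_equal(ensemble_msd(list(ca, cb), "uniform")$msd_um2, 2)
  # pair-count weighting: (1*1 + 3*3) / 4
  expect_equal(ensemble_msd(list(ca, cb), "by_pairs")$msd_um2, 2.5)
  expect_error(ensemble_msd(list()), "no MSD curves")
})

test_that("fit_powerlaw inverts noiseless power-law curves exactly", {
  # the worked example: D = 0.1, alpha = 0.5 on the 17-200 ms grid
  fit <- fit_powerlaw(powerlaw_curve(0.1, 0.5))
  expect_equal(fit$alpha, 0.5, tolerance = 1e-12)
  expect_equal(fit$D, 0.1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_true(fit$passed_gate)

  # exact Brownian curve: alpha = 1 exactly
  expect_equal(fit_powerlaw(powerlaw_curve(0.05, 1))$alpha, 1,
               tolerance = 1e-12)

  # grid over the (D, alpha) plane
  for (D in 10^seq(-3, 0, length.out = 5))
    for (alpha in seq(0.2, 1.8, length.out = 5)) {
      fit <- fit_powerlaw(powerlaw_curve(D, alpha))
      expect_equal(fit$alpha, alpha, tolerance = 1e-9)
      expect_equal(fit$D, D, tolerance = 1e-9 * D)
    }
})

test_that("fits with too few usable delays are flagged failed, not passed", {
  curve <- powerlaw_curve(0.1, 1, n = 2)
  fit <- fit_powerlaw(curve)
  expect_true(fit$failed)
  expect_false(fit$passed_gate)

  # zero-MSD delays are excluded before counting
  c0 <- powerlaw_curve(0.1, 1, n = 4)
  c0$msd_um2[1:2] <- 0
  expect_true(fit_powerlaw(c0)$failed)
})

test_that("the -log10 D_app series separates Brownian from subdiffusive
           curves", {
  s <- logD_vs_time(powerlaw_curve(0.1, 1))
  expect_equal(s$neg_log10_D_app, rep(1, nrow(s)), tolerance = 1e-12)

  s2 <- logD_vs_time(powerlaw_curve(0.1, 0.5))
  expect_true(all(diff(s2$neg_log10_D_app) > 0))
})

test_that("motion classes follow the alpha band", {
  band <- c(0.9, 1.1)
  expect_equal(classify_motion(0.5, band), "anomalous_confined")
  expect_equal(classify_motion(1.0, band), "brownian")
  expect_equal(classify_motion(1.3, band), "directed")
  expect_equal(classify_motion(c(0.89, 0.9, 1.1, 1.11), band),
               c("anomalous_confined", "brownian", "brownian", "directed"))
})

test_that("confinement fits recover the generating parameters and refuse
           non-plateauing curves", {
  tau <- (1:60) * dt
  curve <- structure(
    data.frame(tau_s = tau, msd_um2 = 0.04 * (1 - exp(-tau / 0.1)),
               n_pairs = 50L),
    class = c("msd_curve", "data.frame"), frame_interval = dt)
  fit <- confinement_radius(curve)
  expect_equal(fit$R_c_um, 0.2, tolerance = 1e-6)
  expect_equal(fit$tau_c_s, 0.1, tolerance = 1e-6)
  expect_gt(fit$r2, 0.999)

  expect_error(confinement_radius(powerlaw_curve(0.1, 1, n = 60)),
               "plateau")
})

test_that("fit_tracks ties the per-track pieces together", {
  gt <- simulate_cohort(list(list(model = brownian_model(0.1), n = 8)),
                        n_steps = 300, dt = dt, seed = 17)
  fits <- fit_tracks(gt)
  expect_equal(nrow(fits), 8)
  expect_true(all(c("track_id", "D", "neg_log10_D", "alpha", "r2",
                    "motion_class") %in% names(fits)))
  expect_equal(fits$neg_log10_D, -log10(fits$D))
  fr <- class_fractions(fits)
  expect_equal(sum(fr$fraction), 1)
})
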