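# Deterministic child seed for track i under a root seed, so that adding
# tracks to a cohort never perturbs existing ones.  Simple LCG-style mix;
# all intermediates stay below 2^53 so double arithmetic is exact.
child_seed <- function(root, i) {
  as.integer((as.numeric(root %% 2147483647L) * 48271 + 104729 * i) %%
               2147483647) + 1L
}

# Exact fractional Gaussian noise (unit grid, unit variance scale) via
# Davies-Harte circulant embedding; falls back to Cholesky if the embedding
# spectrum is not non-negative (rare for H in (0,1)).
fgn_sample <- function(n, H) {
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n))
  if (n == 1L) return(stats::rnorm(1))  # single increment, unit variance
  k <- 0:n
  gamma <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                    abs(k - 1)^(2 * H))
  # circulant first row: gamma_0..gamma_n, gamma_{n-1}..gamma_1
  c_row <- c(gamma, gamma[n:2])
  lambda <- Re(stats::fft(c_row))
  if (min(lambda) < -1e-9 * max(lambda)) return(fgn_cholesky(n, H, gamma))
  lambda[lambda < 0] <- 0
  m <- 2L * n
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  # enforce Hermitian symmetry so the inverse FFT is real
  z[1] <- complex(real = Re(z[1]) * sqrt(2), imaginary = 0)
  z[n + 1] <- complex(real = Re(z[n + 1]) * sqrt(2), imaginary = 0)
  z[(n + 2):m] <- Conj(z[n:2])
  w <- stats::fft(sqrt(lambda / (2 * m)) * z)
  Re(w)[1:n]
}

fgn_cholesky <- function(n, H, gamma) {
  idx <- abs(outer(1:n, 1:n, "-")) + 1L
  L <- chol(matrix(gamma[idx], n, n))
  as.vector(crossprod(L, stats::rnorm(n)))
}

#' Simulate one single-particle trajectory
#'
#' Generates a 2D trajectory of `n_steps` positions on a uniform time grid
#' under one of the four motion models.  Increment statistics follow the
#' MSD conventions used throughout the package (d = 2):
#' \describe{
#'   \item{brownian}{independent Gaussian increments per axis with variance
#'     2 D dt, so MSD(tau) = 4 D tau.}
#'   \item{anomalous}{fractional Brownian motion per axis with Hurst
#'     exponent H = alpha/2, scaled so that E MSD(tau) = 4 D tau^alpha
#'     (D in um^2/s^alpha).  Synthesis is exact (Davies-Harte circulant
#'     embedding of the increment covariance).}
#'   \item{confined}{Brownian increments reflected radially at the boundary
#'     of a disk of radius `R_c` centered on the start position; the frame
#'     interval is internally subdivided so the per-substep RMS step is at
#'     most R_c/8, which keeps the stationary distribution uniform on the
#'     disk and the long-lag MSD plateau at R_c^2.}
#'   \item{directed}{Brownian increments plus a deterministic drift
#'     v dt along `heading`.}
#' }
#'
#' @param model a [motion_model] object.
#' @param n_steps number of positions (>= 2).
#' @param dt frame interval in seconds.
#' @param seed integer seed; the trajectory is deterministic given the seed.
#' @param origin numeric length-2, start position in um.
#'
#' @return A data.frame with columns `frame` (0-based), `t_s`, `x_um`,
#'   `y_um`.
#' @examples
#' tr <- simulate_track(brownian_model(0.1), n_steps = 100, dt = 0.017,
#'                      seed = 1)
#' head(tr)
#' @export
simulate_track <- function(model, n_steps, dt, seed,
                           origin = c(0, 0)) {
  validate_motion_model(model)
  if (!is.numeric(n_steps) || n_steps < 2)
    stop("field 'n_steps' must be >= 2")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("field 'dt' must be a positive frame interval in seconds")
  n_steps <- as.integer(n_steps)
  set.seed(as.integer(seed))
  n_inc <- n_steps - 1L

  xy <- switch(model$kind,
    brownian = {
      sd_step <- sqrt(2 * model$D * dt)
      cbind(cumsum(c(0, stats::rnorm(n_inc, sd = sd_step))),
            cumsum(c(0, stats::rnorm(n_inc, sd = sd_step))))
    },
    anomalous = {
      H <- model$alpha / 2
      # unit-grid fGN scaled to physical time: B_H(n dt) ~ dt^H B_H(n)
      scale <- sqrt(2 * model$D) * dt^H
      cbind(cumsum(c(0, scale * fgn_sample(n_inc, H))),
            cumsum(c(0, scale * fgn_sample(n_inc, H))))
    },
    confined = simulate_confined(model, n_steps, dt),
    directed = {
      sd_step <- sqrt(2 * model$D * dt)
      drift <- model$v * dt * c(cos(model$heading), sin(model$heading))
      cbind(cumsum(c(0, stats::rnorm(n_inc, sd = sd_step) + drift[1])),
            cumsum(c(0, stats::rnorm(n_inc, sd = sd_step) + drift[2])))
    },
    stop("unknown motion model kind: ", model$kind))

  data.frame(frame = 0:(n_steps - 1L),
             t_s = (0:(n_steps - 1L)) * dt,
             x_um = xy[, 1] + origin[1],
             y_um = xy[, 2] + origin[2])
}

# Brownian motion in a reflecting disk centered at the origin.  Substeps
# keep the RMS step small relative to R_c so radial reflection approximates
# continuous reflecting boundary conditions well.
simulate_confined <- function(model, n_steps, dt) {
  R <- model$R_c
  rms_target <- R / 8
  n_sub <- max(1L, ceiling(2 * model$D * dt / rms_target^2))
  sd_sub <- sqrt(2 * model$D * dt / n_sub)
  n_inc <- (n_steps - 1L) * n_sub
  dx <- stats::rnorm(n_inc, sd = sd_sub)
  dy <- stats::rnorm(n_inc, sd = sd_sub)
  pos <- matrix(0, n_steps, 2)
  cur <- c(0, 0)
  k <- 1L
  for (i in seq_len(n_steps - 1L)) {
    for (s in seq_len(n_sub)) {
      cur <- cur + c(dx[k], dy[k])
      k <- k + 1L
      r <- sqrt(sum(cur^2))
      if (r > R) cur <- cur * (2 * R - r) / r  # radial reflection
    }
    pos[i + 1L, ] <- cur
  }
  pos
}

#' Simulate a cohort of trajectories with known ground truth
#'
#' Draws independent tracks from a list of motion models (one imaging
#' condition's worth of particles), with start positions uniform over a
#' rectangular field.  Each track gets its own child RNG stream derived
#' from the root seed, so enlarging the cohort never changes existing
#' tracks.
#'
#' @param models list of `list(model = <motion_model>, n = <count>)` pairs,
#'   or a single [motion_model] (taken as `n = 1`).
#' @param n_steps,dt as in [simulate_track()].
#' @param seed root integer seed.
#' @param field_um numeric length-2 `(width, height)` of the field in um;
#'   defaults to the 500 px x 65 nm TIRF field (32.5 um square).
#'
#' @return A `data.frame` of class `spt_tracks` with columns `track_id`,
#'   `frame`, `t_s`, `x_um`, `y_um`, `model`.
#' @examples
#' gt <- simulate_cohort(list(list(model = brownian_model(0.1), n = 3)),
#'                       n_steps = 50, dt = 0.017, seed = 7)
#' table(gt$model)
#' @export
simulate_cohort <- function(models, n_steps, dt, seed,
                            field_um = c(32.5, 32.5)) {
  if (inherits(models, "motion_model"))
    models <- list(list(model = models, n = 1L))
  if (length(models) == 0) stop("field 'models' must not be empty")
  counts <- vapply(models, function(m) as.integer(m$n), integer(1))
  if (any(counts < 1)) stop("model counts must be >= 1")
  lapply(models, function(m) validate_motion_model(m$model))

  n_tracks <- sum(counts)
  kinds <- rep(vapply(models, function(m) m$model$kind, character(1)),
               counts)
  model_of <- rep(seq_along(models), counts)

  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    # separate child streams for the start position and the increments,
    # keyed only by (seed, i): enlarging the cohort leaves earlier tracks
    # untouched
    set.seed(child_seed(seed, 2L * i))
    start_i <- stats::runif(2) * field_um
    tr <- simulate_track(models[[model_of[i]]]$model, n_steps, dt,
                         seed = child_seed(seed, 2L * i + 1L),
                         origin = start_i)
    tr$track_id <- i
    tr$model <- kinds[i]
    out[[i]] <- tr
  }
  res <- do.call(rbind, out)[, c("track_id", "frame", "t_s",
                                 "x_um", "y_um", "model")]
  structure(res, class = c("spt_tracks", "data.frame"),
            frame_interval = dt, field_um = field_um)
}

#' Acquisition configuration for movie rendering
#'
#' Defaults reproduce the TIRF acquisition regime the pipeline targets:
#' 65 nm pixels, 58.8 Hz (17 ms frame interval), 500 x 500 px field.
#'
#' @param pixel_size_nm pixel size in nm.
#' @param frame_interval_s frame interval in seconds.
#' @param n_frames number of frames (>= 2).
#' @param field_px integer length-2 `(height, width)` in pixels.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels.
#' @param photons_per_spot expected integrated photon count per spot per
#'   frame.  The defaults give a peak amplitude of about
#'   `photons_per_spot / (2 pi psf_sigma_px^2) ~ 94` counts over a
#'   background of 100, i.e. a signal-to-noise ratio (peak over background
#'   shot-noise sd) of about 10, typical of single-fluorophore TIRF.
#' @param background mean background level in photons per pixel.
#' @param read_noise_sd Gaussian read noise standard deviation (counts);
#'   0 disables it.
#'
#' @return list of class `acquisition_config`.
#' @export
acquisition_config <- function(pixel_size_nm = 65,
                               frame_interval_s = 1 / 58.8,
                               n_frames = 200L,
                               field_px = c(500L, 500L),
                               psf_sigma_px = 1.3,
                               photons_per_spot = 1000,
                               background = 100,
                               read_noise_sd = 0) {
  stopifnot(pixel_size_nm > 0, frame_interval_s > 0, n_frames >= 2,
            psf_sigma_px > 0, all(field_px >= 1),
            photons_per_spot >= 0, background >= 0, read_noise_sd >= 0)
  structure(list(pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 field_px = as.integer(field_px),
                 psf_sigma_px = psf_sigma_px,
                 photons_per_spot = photons_per_spot,
                 background = background,
                 read_noise_sd = read_noise_sd),
            class = "acquisition_config")
}

#' Render ground-truth tracks into a TIRF-like movie
#'
#' Each particle present in a frame is rendered as an isotropic 2D Gaussian
#' (integrated over pixel areas via the Gaussian CDF) of expected integrated
#' intensity `photons_per_spot` on a uniform background; per-pixel shot
#' noise is Poisson and optional additive Gaussian read noise can be added.
#' Particles whose centers leave the field keep their true trajectories but
#' are only rendered while inside, mimicking particles exiting the TIRF
#' footprint.
#'
#' Pixel convention: pixel (row i, col j), 0-based, has its center at
#' physical position ((j + 0.5) px, (i + 0.5) px).
#'
#' @param truth `spt_tracks` data.frame from [simulate_cohort()] (positions
#'   in um).
#' @param acq [acquisition_config()].
#' @param seed integer seed for the noise; rendering is deterministic
#'   given the seed.
#' @param noise if `FALSE`, return noiseless expected intensities.
#'
#' @return An `spt_movie` object: list with `frames` (3D array t, y, x),
#'   `pixel_size_nm`, `frame_interval_s`.
#' @export
render_movie <- function(truth, acq = acquisition_config(), seed = 1L,
                         noise = TRUE) {
  if (any(acq$field_px < 1)) stop("field must have positive area")
  if (acq$photons_per_spot < 0) stop("photon count must be >= 0")
  px_um <- acq$pixel_size_nm / 1000
  ny <- acq$field_px[1]; nx <- acq$field_px[2]
  nt <- acq$n_frames
  frames <- array(acq$background, dim = c(nt, ny, nx))
  sig <- acq$psf_sigma_px
  half <- ceiling(4 * sig)

  if (nrow(truth) > 0) {
    tr <- truth[truth$frame < nt, , drop = FALSE]
    # pixel coordinates of centers (0-based, center-of-pixel convention)
    cx <- tr$x_um / px_um - 0.5
    cy <- tr$y_um / px_um - 0.5
    inside <- cx >= -half & cx <= nx - 1 + half &
              cy >= -half & cy <= ny - 1 + half
    tr <- tr[inside, , drop = FALSE]; cx <- cx[inside]; cy <- cy[inside]
    for (s in seq_len(nrow(tr))) {
      f <- tr$frame[s] + 1L
      j0 <- max(0L, floor(cx[s]) - half); j1 <- min(nx - 1L, floor(cx[s]) + half)
      i0 <- max(0L, floor(cy[s]) - half); i1 <- min(ny - 1L, floor(cy[s]) + half)
      if (j0 > j1 || i0 > i1) next
      jj <- j0:j1; ii <- i0:i1
      # integral of the Gaussian over each pixel via CDF differences
      gx <- stats::pnorm(jj + 0.5, cx[s], sig) - stats::pnorm(jj - 0.5, cx[s], sig)
      gy <- stats::pnorm(ii + 0.5, cy[s], sig) - stats::pnorm(ii - 0.5, cy[s], sig)
      frames[f, ii + 1L, jj + 1L] <- frames[f, ii + 1L, jj + 1L] +
        acq$photons_per_spot * outer(gy, gx)
    }
  }

  if (noise) {
    set.seed(as.integer(seed))
    n <- length(frames)
    frames[] <- stats::rpois(n, lambda = frames)
    if (acq$read_noise_sd > 0)
      frames[] <- frames + stats::rnorm(n, sd = acq$read_noise_sd)
    frames[frames < 0] <- 0
  }
  frames[] <- pmin(frames, 65535)

  structure(list(frames = frames,
                 pixel_size_nm = acq$pixel_size_nm,
                 frame_interval_s = acq$frame_interval_s),
            class = "spt_movie")
}

#' @export
print.spt_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<spt_movie> %d frames, %d x %d px, %.0f nm/px, %.4f s/frame\n",
    d[1], d[2], d[3], x$pixel_size_nm, x$frame_interval_s))
  invisible(x)
}
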