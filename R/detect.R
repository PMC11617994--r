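# Separable convolution with edge replication: out = conv(ky) o conv(kx).
# Kernels must have odd length.
conv2_sep <- function(img, ky, kx) {
  hy <- (length(ky) - 1L) %/% 2L
  hx <- (length(kx) - 1L) %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  pad <- img[c(rep(1L, hy), 1:ny, rep(ny, hy)),
             c(rep(1L, hx), 1:nx, rep(nx, hx)), drop = FALSE]
  # convolve along rows (y) by banded matrix product
  My <- matrix(0, ny, ny + 2L * hy)
  for (k in seq_along(ky)) My[cbind(1:ny, 1:ny + (k - 1L))] <- ky[k]
  Mx <- matrix(0, nx + 2L * hx, nx)
  for (k in seq_along(kx)) Mx[cbind(1:nx + (k - 1L), 1:nx)] <- kx[k]
  My %*% pad %*% Mx
}

gauss_kernel <- function(sigma, half) {
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# second derivative of the (normalized) Gaussian; re-centered to sum to
# zero exactly so constant images give an exactly zero LoG response
gauss_d2_kernel <- function(sigma, half) {
  x <- (-half):half
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  d2 <- g * (x^2 - sigma^2) / sigma^4
  d2 - mean(d2)
}

# Scale-normalized Laplacian-of-Gaussian response, sign-flipped so that
# bright blobs of radius ~ sigma*sqrt(2) give positive maxima:
#   R = -sigma^2 * (Gxx + Gyy) * I
log_response <- function(img, sigma) {
  half <- max(2L, ceiling(4 * sigma))
  g <- gauss_kernel(sigma, half)
  d2 <- gauss_d2_kernel(sigma, half)
  -sigma^2 * (conv2_sep(img, d2, g) + conv2_sep(img, g, d2))
}

# 3x3 median filter via a pmin/pmax selection network, exact on raw counts.
median3x3 <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- img[c(1L, 1:ny, ny), c(1L, 1:nx, nx)]
  s <- vector("list", 9L)
  k <- 1L
  for (di in 0:2) for (dj in 0:2) {
    s[[k]] <- pad[di + 1:ny, dj + 1:nx]
    k <- k + 1L
  }
  swap <- function(i, j) {
    lo <- pmin(s[[i]], s[[j]]); hi <- pmax(s[[i]], s[[j]])
    s[[i]] <<- lo; s[[j]] <<- hi
  }
  # 19-comparator median-of-9 network (Paeth)
  idx <- list(c(1,2),c(4,5),c(7,8),c(2,3),c(5,6),c(8,9),c(1,2),c(4,5),
              c(7,8),c(1,4),c(4,7),c(4,5),c(2,5),c(5,8),c(5,6),c(3,5),
              c(5,7),c(3,5),c(5,6))
  for (p in idx) swap(p[1], p[2])
  s[[5]]
}

#' Detect spots with a Laplacian-of-Gaussian filter
#'
#' Per-frame detection: optional 3x3 median pre-filter, scale-normalized
#' LoG filtering at sigma = spot_diameter / (2 sqrt(2)), strict 3x3 local
#' maxima of the response above `quality_threshold`, then subpixel
#' refinement by per-axis quadratic interpolation of the response (with an
#' intensity-weighted centroid fallback when the parabola is degenerate).
#' Candidates within ceiling(2 sigma) px of the border are discarded; when
#' two maxima fall within spot_diameter/2 of each other the one with higher
#' quality is kept (ties broken by frame, y, x order).
#'
#' Coordinates are physical um, with pixel (i, j) (0-based) centered at
#' ((j + 0.5) px, (i + 0.5) px).
#'
#' @param movie an `spt_movie` (see [render_movie()] or
#'   [read_movie_tiff()]).
#' @param spot_diameter_um expected spot diameter in um (>= 2 px).
#' @param quality_threshold numeric threshold on the LoG response, or
#'   `"auto"` to use [auto_threshold()].
#' @param use_median_filter apply the 3x3 median pre-filter (default TRUE).
#'
#' @return data.frame of class `spt_localizations` with columns `frame`
#'   (0-based), `x_um`, `y_um`, `quality` (LoG response at the maximum) and
#'   `intensity` (background-subtracted integrated signal).
#' @export
detect_spots <- function(movie, spot_diameter_um,
                         quality_threshold = "auto",
                         use_median_filter = TRUE) {
  stopifnot(inherits(movie, "spt_movie"))
  nt <- dim(movie$frames)[1]
  if (nt < 1) stop("movie is empty")
  px_um <- movie$pixel_size_nm / 1000
  sigma <- spot_diameter_um / (2 * sqrt(2)) / px_um
  if (spot_diameter_um / px_um < 2)
    stop("spot_diameter_um must be at least 2 pixels")
  if (identical(quality_threshold, "auto"))
    quality_threshold <- auto_threshold(movie, spot_diameter_um,
                                        use_median_filter = use_median_filter)
  if (!is.finite(quality_threshold))
    stop("quality_threshold must be finite")

  border <- ceiling(2 * sigma)
  min_sep2 <- (spot_diameter_um / 2 / px_um)^2
  out <- vector("list", nt)
  for (f in seq_len(nt)) {
    img <- movie$frames[f, , ]
    if (use_median_filter) img <- median3x3(img)
    resp <- log_response(img, sigma)
    cand <- local_maxima(resp, quality_threshold, border)
    if (nrow(cand) == 0) next
    cand <- suppress_duplicates(cand, min_sep2)
    ref <- refine_subpixel(resp, img, cand, sigma)
    out[[f]] <- data.frame(frame = f - 1L,
                           x_um = (ref$x + 0.5) * px_um,
                           y_um = (ref$y + 0.5) * px_um,
                           quality = cand$q,
                           intensity = ref$intensity)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
               quality = numeric(), intensity = numeric())
  structure(res, class = c("spt_localizations", "data.frame"),
            pixel_size_nm = movie$pixel_size_nm,
            frame_interval = movie$frame_interval_s,
            threshold = quality_threshold)
}

# strict 3x3 local maxima above threshold, away from the border;
# returns 0-based pixel coordinates and the response value
local_maxima <- function(resp, thr, border) {
  ny <- nrow(resp); nx <- ncol(resp)
  lo <- border + 1L
  if (ny < 2L * lo || nx < 2L * lo)
    return(data.frame(i = integer(), j = integer(), q = numeric()))
  ii <- lo:(ny - lo + 1L); jj <- lo:(nx - lo + 1L)
  core <- resp[ii, jj]
  is_max <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & core > resp[ii + di, jj + dj]
  }
  w <- which(is_max, arr.ind = TRUE)
  data.frame(i = ii[w[, 1]] - 1L, j = jj[w[, 2]] - 1L,
             q = core[w])
}

# keep the higher-quality candidate of any pair closer than sqrt(min_sep2);
# deterministic: sort by quality desc, then (i, j) ascending
suppress_duplicates <- function(cand, min_sep2) {
  ord <- order(-cand$q, cand$i, cand$j)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (a in seq_len(nrow(cand))) {
    if (!keep[a]) next
    if (a < nrow(cand)) {
      b <- (a + 1L):nrow(cand)
      d2 <- (cand$i[b] - cand$i[a])^2 + (cand$j[b] - cand$j[a])^2
      keep[b[d2 < min_sep2]] <- FALSE
    }
  }
  cand[keep, , drop = FALSE]
}

# per-axis quadratic interpolation of the response maximum; centroid
# fallback; also integrates background-subtracted intensity in a window
refine_subpixel <- function(resp, img, cand, sigma) {
  n <- nrow(cand)
  x <- numeric(n); y <- numeric(n); intensity <- numeric(n)
  half <- ceiling(2 * sigma)
  for (s in seq_len(n)) {
    i <- cand$i[s] + 1L; j <- cand$j[s] + 1L  # 1-based
    dxs <- parabola_offset(resp[i, j - 1L], resp[i, j], resp[i, j + 1L])
    dys <- parabola_offset(resp[i - 1L, j], resp[i, j], resp[i + 1L, j])
    if (is.na(dxs) || is.na(dys)) {
      ii <- (i - half):(i + half); jj <- (j - half):(j + half)
      win <- img[ii, jj]
      bg <- stats::median(c(win[1, ], win[nrow(win), ],
                            win[, 1], win[, ncol(win)]))
      w <- pmax(win - bg, 0)
      if (sum(w) > 0) {
        dxs <- sum(t(w) * (jj - j)) / sum(w)
        dys <- sum(w * (ii - i)) / sum(w)
      } else dxs <- dys <- 0
    }
    x[s] <- cand$j[s] + dxs
    y[s] <- cand$i[s] + dys
    ii <- (i - half):(i + half); jj <- (j - half):(j + half)
    win <- img[ii, jj]
    bg <- stats::median(c(win[1, ], win[nrow(win), ],
                          win[, 1], win[, ncol(win)]))
    intensity[s] <- sum(win) - length(win) * bg
  }
  list(x = x, y = y, intensity = intensity)
}

# offset of the vertex of the parabola through (-1,a),(0,b),(1,c); NA if
# degenerate or outside (-1, 1)
parabola_offset <- function(a, b, c) {
  den <- a - 2 * b + c
  if (!is.finite(den) || den >= 0) return(NA_real_)
  off <- 0.5 * (a - c) / den
  if (abs(off) > 1) NA_real_ else off
}

#' Data-driven LoG quality threshold
#'
#' Returns `median(response) + k * MAD(response)` over a deterministic
#' sample of frames (at most `max_frames`, evenly spaced).  The default
#' k = 8 keeps false positives on pure-noise movies near zero while
#' retaining spots at signal-to-noise ratios of a few and above; it can be
#' overridden per movie, reflecting per-acquisition threshold tuning.
#'
#' @param movie an `spt_movie`.
#' @param spot_diameter_um expected spot diameter in um.
#' @param k robust multiplier (default 8).
#' @param max_frames maximum number of frames sampled (default 20).
#' @param use_median_filter apply the 3x3 median pre-filter first.
#' @return a single numeric threshold.
#' @export
auto_threshold <- function(movie, spot_diameter_um, k = 8,
                           max_frames = 20L, use_median_filter = TRUE) {
  stopifnot(inherits(movie, "spt_movie"))
  nt <- dim(movie$frames)[1]
  px_um <- movie$pixel_size_nm / 1000
  sigma <- spot_diameter_um / (2 * sqrt(2)) / px_um
  idx <- unique(round(seq(1, nt, length.out = min(nt, max_frames))))
  vals <- lapply(idx, function(f) {
    img <- movie$frames[f, , ]
    if (use_median_filter) img <- median3x3(img)
    as.vector(log_response(img, sigma))
  })
  v <- unlist(vals)
  stats::median(v) + k * stats::mad(v)
}
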