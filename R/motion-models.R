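#' Motion models for trajectory simulation
#'
#' Constructors for the four motion regimes distinguished by the anomalous
#' exponent alpha of the mean-square displacement MSD(tau) = 2 d D tau^alpha
#' (d = 2 for membrane diffusion): Brownian (alpha = 1), anomalous
#' subdiffusion (alpha < 1, fractional Brownian motion), confined diffusion
#' (Brownian motion inside a reflecting disk) and directed motion
#' (Brownian motion plus constant drift, alpha > 1 at long lags).
#'
#' @param D diffusion coefficient. Units are um^2/s for `brownian_model`,
#'   `confined_model` and `directed_model`; for `anomalous_model` D is the
#'   generalized coefficient in um^2/s^alpha.
#' @param alpha target anomalous exponent, 0 < alpha <= 2.
#' @param R_c confinement radius in um (radius of the reflecting disk).
#' @param v drift speed in um/s.
#' @param heading drift direction in radians.
#'
#' @return An object of class `motion_model`: a list with a `kind` field
#'   (`"brownian"`, `"anomalous"`, `"confined"` or `"directed"`) plus the
#'   model parameters.
#'
#' @examples
#' brownian_model(D = 0.1)
#' anomalous_model(D = 0.05, alpha = 0.5)
#' @name motion_model
NULL

new_motion_model <- function(kind, ...) {
  m <- structure(list(kind = kind, ...), class = "motion_model")
  validate_motion_model(m)
  m
}

validate_motion_model <- function(m) {
  if (!inherits(m, "motion_model") || is.null(m$kind))
    stop("not a motion_model object")
  if (!is.numeric(m$D) || length(m$D) != 1L || !is.finite(m$D) || m$D < 0)
    stop("motion model field 'D' must be a single finite number >= 0")
  if (m$kind == "anomalous") {
    if (!is.numeric(m$alpha) || !is.finite(m$alpha) ||
        m$alpha <= 0 || m$alpha > 2)
      stop("motion model field 'alpha' must satisfy 0 < alpha <= 2")
  }
  if (m$kind == "confined") {
    if (!is.numeric(m$R_c) || !is.finite(m$R_c) || m$R_c <= 0)
      stop("motion model field 'R_c' must be > 0")
  }
  if (m$kind == "directed") {
    if (!is.numeric(m$v) || !is.finite(m$v) || m$v < 0)
      stop("motion model field 'v' must be >= 0")
    if (!is.numeric(m$heading) || !is.finite(m$heading))
      stop("motion model field 'heading' must be a finite angle in radians")
  }
  invisible(m)
}

#' @rdname motion_model
#' @export
brownian_model <- function(D) new_motion_model("brownian", D = D)

#' @rdname motion_model
#' @export
anomalous_model <- function(D, alpha)
  new_motion_model("anomalous", D = D, alpha = alpha)

#' @rdname motion_model
#' @export
confined_model <- function(D, R_c)
  new_motion_model("confined", D = D, R_c = R_c)

#' @rdname motion_model
#' @export
directed_model <- function(D, v, heading = 0)
  new_motion_model("directed", D = D, v = v, heading = heading)

#' @export
print.motion_model <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat("<motion_model> ", x$kind, ": ",
      paste(names(pars), unlist(pars), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
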