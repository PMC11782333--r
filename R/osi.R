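#' Construct a wall-shear-stress field
#'
#' Per-element WSS vector time series over one cardiac cycle on a
#' triangulated lumen surface, with element areas and an optional region
#' of interest (ROI). The ROI is the ~4 cm patch around the anastomosis
#' over which area fractions are reported; when no mask is supplied, the
#' whole mesh is the ROI.
#'
#' @param times Strictly increasing time samples (s) spanning one cycle
#'   (length >= 2).
#' @param tau Numeric array `n_elements x n_times x 3` of shear vectors
#'   (Pa), finite everywhere.
#' @param element_areas Per-element areas (mm^2), all > 0.
#' @param roi_mask Optional logical vector flagging ROI elements; defaults
#'   to all `TRUE`.
#' @return A `wss_field` object.
#' @export
wss_field <- function(times, tau, element_areas, roi_mask = NULL) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("need at least 2 time samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(dim(tau)) != 3L || dim(tau)[3] != 3L)
    stop("tau must be an n_elements x n_times x 3 array")
  if (dim(tau)[2] != length(times))
    stop("tau second dimension must match length(times)")
  if (!all(is.finite(tau))) stop("tau must be finite everywhere")
  element_areas <- as.numeric(element_areas)
  if (length(element_areas) != dim(tau)[1])
    stop("element_areas length must match the number of elements")
  if (any(element_areas <= 0)) stop("all element areas must be positive")
  if (is.null(roi_mask)) roi_mask <- rep(TRUE, dim(tau)[1])
  if (length(roi_mask) != dim(tau)[1])
    stop("roi_mask length must match the number of elements")
  structure(list(times = times, tau = tau,
                 element_areas = element_areas,
                 roi_mask = as.logical(roi_mask)),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %d elements, %d time samples over %.3g s, ROI %d elements\n",
              dim(x$tau)[1], length(x$times), diff(range(x$times)),
              sum(x$roi_mask)))
  invisible(x)
}

#' Oscillatory shear index per element
#'
#' The OSI quantifies direction reversal of the wall shear vector over a
#' cardiac cycle of period T:
#' \deqn{OSI = 0.5 (1 - ||\int_0^T \tau\,dt|| / \int_0^T ||\tau||\,dt)}
#' 0 means unidirectional shear, 0.5 purely oscillatory (zero time
#' average). Time integrals use the trapezoidal rule over the supplied
#' cycle. Elements whose shear is identically zero over the whole cycle
#' have an undefined ratio; they are reported as OSI = 0 with a warning.
#'
#' @param field A `wss_field` (one cardiac cycle).
#' @return An `osi_field`: list with per-element `osi` in \[0, 0.5\].
#' @export
compute_osi <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  t <- field$times
  w <- .trapezoid_weights(t)
  # mean vector integral per component, and integral of the magnitude
  int_vec <- sapply(1:3, function(k) as.numeric(field$tau[, , k] %*% w))
  int_vec <- matrix(int_vec, ncol = 3)
  mag <- sqrt(field$tau[, , 1]^2 + field$tau[, , 2]^2 + field$tau[, , 3]^2)
  int_mag <- as.numeric(mag %*% w)
  osi <- numeric(nrow(int_vec))
  zero <- int_mag == 0
  if (any(zero))
    warning(sum(zero), " element(s) with identically zero shear; OSI set to 0")
  nz <- !zero
  osi[nz] <- 0.5 * (1 - sqrt(rowSums(int_vec[nz, , drop = FALSE]^2)) / int_mag[nz])
  # trapezoid round-off can push the ratio a hair past 1
  osi <- pmin(pmax(osi, 0), 0.5)
  structure(list(osi = osi), class = "osi_field")
}

.trapezoid_weights <- function(t) {
  n <- length(t)
  dt <- diff(t)
  w <- numeric(n)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-(n - 1)] + dt[-1]) / 2
  w
}

#' Percentage of ROI area with OSI above a threshold
#'
#' Area-weighted fraction of the region of interest whose OSI strictly
#' exceeds the threshold (default 0.1, the conventional cutoff for
#' disturbed flow), as a percentage.
#'
#' @param osi An `osi_field` aligned element-wise with `field`.
#' @param field The `wss_field` providing areas and the ROI mask.
#' @param threshold Dimensionless OSI threshold; strict `>` comparison.
#' @return Percentage in \[0, 100\].
#' @export
high_osi_area_percent <- function(osi, field, threshold = 0.1) {
  stopifnot(inherits(osi, "osi_field"), inherits(field, "wss_field"))
  if (length(osi$osi) != length(field$element_areas))
    stop("osi and field are not aligned element-wise")
  roi <- field$roi_mask
  if (!any(roi)) stop("region of interest is empty")
  a <- field$element_areas[roi]
  100 * sum(a[osi$osi[roi] > threshold]) / sum(a)
}
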