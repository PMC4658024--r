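#' @useDynLib marstreak, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parallel-beam acquisition geometry
#'
#' 2D parallel-beam geometry: `n_angles` views uniformly spaced over
#' [0, 180) degrees (counter-clockwise, image center as isocenter) and a
#' linear detector of `n_detectors` elements spaced `det_spacing` cm apart,
#' centered on the isocenter.
#'
#' @param n_angles Number of views over half a turn (>= 90 for any scored
#'   experiment; smaller values are allowed for toy tests).
#' @param n_detectors Number of detector elements; must cover the phantom
#'   diagonal.
#' @param det_spacing Detector pitch in cm.
#' @param pixel_size Reconstruction pixel size in cm.
#' @return An object of class `ct_geometry`.
#' @export
ct_geometry <- function(n_angles, n_detectors, det_spacing, pixel_size) {
  stopifnot(n_angles >= 1, n_detectors >= 2, det_spacing > 0, pixel_size > 0)
  structure(
    list(n_angles = n_angles, n_detectors = n_detectors,
         det_spacing = det_spacing, pixel_size = pixel_size,
         angles = seq(0, pi, length.out = n_angles + 1)[seq_len(n_angles)]),
    class = "ct_geometry"
  )
}

#' Default geometry for a phantom
#'
#' Detector count covers the grid diagonal with margin; pitch equals the
#' pixel size.
#'
#' @param phantom A `ct_phantom`.
#' @param n_angles Number of views (default 180).
#' @return A `ct_geometry`.
#' @export
default_geometry <- function(phantom, n_angles = 180) {
  n <- nrow(phantom$labels)
  n_det <- 2 * ceiling(sqrt(2) * n / 2) + 9  # odd, > diagonal
  ct_geometry(n_angles, n_det, phantom$pixel_size, phantom$pixel_size)
}

geometry_covers <- function(geometry, phantom) {
  n <- nrow(phantom$labels)
  geometry$n_detectors * geometry$det_spacing >=
    sqrt(2) * n * phantom$pixel_size
}

#' Forward-project a phantom into per-material path lengths
#'
#' Discrete Radon transform of each material's indicator map, giving the
#' intersection length (cm) of every ray with that material. Path lengths
#' are energy-independent, so one projection serves both kV channels.
#'
#' @param phantom A `ct_phantom`.
#' @param geometry A `ct_geometry` covering the phantom support.
#' @param step_frac Ray-marching step as a fraction of the pixel size
#'   (Joseph-style sampling); default 0.5.
#' @return Named list of `n_angles x n_detectors` matrices, one per
#'   material present in the phantom.
#' @export
project <- function(phantom, geometry = default_geometry(phantom),
                    step_frac = 0.5) {
  if (!geometry_covers(geometry, phantom)) {
    stop("geometry does not cover the phantom support", call. = FALSE)
  }
  masks <- lapply(material_masks(phantom), function(m) m * 1.0)
  radon_forward_multi(masks, geometry$angles, geometry$n_detectors,
                      geometry$det_spacing, phantom$pixel_size, step_frac)
}

#' Radon transform of an arbitrary image
#'
#' @param image Numeric matrix (values per cm of path, e.g. mu in cm^-1).
#' @param geometry A `ct_geometry`.
#' @param pixel_size Pixel size in cm.
#' @param step_frac Ray-marching step fraction.
#' @return `n_angles x n_detectors` matrix of line integrals.
#' @export
radon <- function(image, geometry, pixel_size = geometry$pixel_size,
                  step_frac = 0.5) {
  radon_forward(image, geometry$angles, geometry$n_detectors,
                geometry$det_spacing, pixel_size, step_frac)
}

# clamp for log line integrals (dimensionless); ~e-60 transmitted fraction
P_CLAMP <- 60

#' Acquire a (possibly noisy) polyenergetic sinogram
#'
#' Detected intensity per ray is
#' \eqn{I = N_0 \sum_b w_b \exp(-\sum_m \mu_m(E_b) t_m)} over the spectrum
#' bins; in noisy mode a Poisson draw of \eqn{I} is floored at one count
#' before the log (detector electronic floor), reproducing photon
#' starvation behind thick metal. The stored sinogram holds
#' \eqn{\ln(N_0 / I)}. Noiseless all-absorbing rays are clamped at a log
#' attenuation of 60 and a warning is raised.
#'
#' @param phantom A `ct_phantom`.
#' @param geometry A `ct_geometry`.
#' @param spectrum A `ct_spectrum` from [make_spectrum()].
#' @param n0 Photons per ray at the source, or `NULL` for a noiseless
#'   acquisition.
#' @param seed Seed for the Poisson draw (required when `n0` is finite).
#' @param paths Optional precomputed [project()] output (reused across
#'   channels and noise realizations).
#' @return An object of class `ct_sinogram`: list with `values`
#'   (`n_angles x n_detectors` log line integrals), `geometry`,
#'   `kvp_label`, `spectrum`, `pixel_size` and `noise_meta`.
#' @export
acquire <- function(phantom, geometry = default_geometry(phantom), spectrum,
                    n0 = NULL, seed = NULL, paths = NULL) {
  if (!is.null(n0) && n0 <= 0) stop("n0 must be positive", call. = FALSE)
  if (is.null(paths)) paths <- project(phantom, geometry)
  mats <- phantom$materials
  # attenuation per material (rows) and energy bin (cols)
  mu <- vapply(names(paths), function(nm) {
    attenuation(nm, spectrum$energies, mats)
  }, numeric(length(spectrum$energies)))
  mu <- matrix(mu, nrow = length(spectrum$energies))  # bins x materials
  p_stack <- vapply(paths, as.vector, numeric(length(paths[[1]])))
  a <- p_stack %*% t(mu)                              # rays x bins
  frac <- exp(-a) %*% spectrum$weights                # transmitted fraction
  if (is.null(n0)) {
    if (any(frac < exp(-P_CLAMP))) {
      warning("all-absorbing rays clamped at log attenuation ", P_CLAMP)
      frac <- pmax(frac, exp(-P_CLAMP))
    }
    values <- -log(frac)
    noise_meta <- list(mode = "noiseless")
  } else {
    if (is.null(seed)) stop("seed required for a noisy acquisition", call. = FALSE)
    i_mean <- n0 * frac
    counts <- with_seed(seed, rpois(length(i_mean), i_mean))
    counts <- pmax(counts, 1)                         # photon floor
    values <- log(n0) - log(counts)
    noise_meta <- list(mode = "poisson", n0 = n0, seed = seed)
  }
  structure(
    list(values = matrix(values, geometry$n_angles, geometry$n_detectors),
         geometry = geometry, kvp_label = spectrum$kvp_label,
         spectrum = spectrum, pixel_size = phantom$pixel_size,
         noise_meta = noise_meta),
    class = "ct_sinogram"
  )
}

#' @export
print.ct_sinogram <- function(x, ...) {
  cat(sprintf("<ct_sinogram %s: %d angles x %d detectors, %s>\n",
              x$kvp_label, x$geometry$n_angles, x$geometry$n_detectors,
              x$noise_meta$mode))
  invisible(x)
}

# discrete convolution kernels of the classic FBP filters (real space)
fbp_kernel <- function(filter_name, n_det, dt) {
  lag <- -(n_det - 1):(n_det - 1)
  h <- switch(
    filter_name,
    ramp = {
      k <- numeric(length(lag))
      k[lag == 0] <- 1 / (4 * dt^2)
      odd <- lag %% 2 != 0
      k[odd] <- -1 / (pi^2 * lag[odd]^2 * dt^2)
      k
    },
    `shepp-logan` = -2 / (pi^2 * dt^2 * (4 * lag^2 - 1)),
    none = as.numeric(lag == 0) / dt,
    stop("unknown filter: ", filter_name, call. = FALSE)
  )
  h
}

#' Filtered back-projection
#'
#' Ramp (Ram-Lak, default) or Shepp-Logan apodized filtering of each view
#' followed by pixel-driven back-projection with linear detector
#' interpolation. Linear in the sinogram. `filter_name = "none"` gives the
#' unfiltered back-projection (for tests).
#'
#' @param sinogram A `ct_sinogram`, or a plain matrix (then `geometry` and
#'   `pixel_size` must be given).
#' @param filter_name `"ramp"`, `"shepp-logan"` or `"none"`.
#' @param n_out Output grid side in pixels; defaults to the largest grid
#'   the detector covers at `pixel_size`.
#' @param geometry,pixel_size Overrides when `sinogram` is a plain matrix.
#' @return Numeric matrix of reconstructed attenuation (cm^-1), with
#'   attribute `pixel_size`.
#' @export
fbp <- function(sinogram, filter_name = c("ramp", "shepp-logan", "none"),
                n_out = NULL, geometry = NULL, pixel_size = NULL) {
  filter_name <- match.arg(filter_name)
  if (inherits(sinogram, "ct_sinogram")) {
    geometry <- sinogram$geometry
    pixel_size <- sinogram$pixel_size
    values <- sinogram$values
  } else {
    values <- sinogram
    if (is.null(geometry)) stop("geometry required for a plain matrix", call. = FALSE)
    if (is.null(pixel_size)) pixel_size <- geometry$pixel_size
  }
  if (any(!is.finite(values))) {
    bad <- which(apply(values, 1, function(r) any(!is.finite(r))))
    stop("non-finite sinogram values in view(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(n_out)) {
    n_out <- floor(geometry$n_detectors * geometry$det_spacing /
                     (sqrt(2) * pixel_size))
  }
  n_det <- geometry$n_detectors
  dt <- geometry$det_spacing
  h <- fbp_kernel(filter_name, n_det, dt)
  pad <- 2^ceiling(log2(length(h) + n_det))
  h_pad <- numeric(pad)
  h_pad[seq_along(h)] <- h
  H <- fft(h_pad)
  p_pad <- matrix(0, pad, geometry$n_angles)
  p_pad[seq_len(n_det), ] <- t(values)
  q <- Re(stats::mvfft(stats::mvfft(p_pad) * H, inverse = TRUE)) / pad
  # 'full' convolution: element n_det..(2 n_det - 1) aligns with detector k
  q <- t(q[n_det:(2 * n_det - 1), , drop = FALSE]) * dt
  img <- radon_back(q, geometry$angles, dt, n_out, pixel_size)
  img <- img * pi / geometry$n_angles
  attr(img, "pixel_size") <- pixel_size
  img
}

#' Convert an attenuation map to Hounsfield units
#'
#' \eqn{HU = 1000 (\mu - \mu_{water}(E)) / \mu_{water}(E)} at the given
#' effective energy.
#'
#' @param mu_map Numeric matrix of attenuation (cm^-1).
#' @param energy Effective energy in keV used for the water anchor.
#' @param pixel_size Pixel size in cm (defaults to the matrix attribute).
#' @param arm_label Provenance label of the reconstruction arm.
#' @return A `ct_image`: list with `hu`, `pixel_size`, `arm_label`,
#'   `energy_meta`.
#' @export
to_hu <- function(mu_map, energy, pixel_size = attr(mu_map, "pixel_size"),
                  arm_label = "raw") {
  muw <- mu_water(energy)
  new_ct_image(1000 * (mu_map - muw) / muw, pixel_size, arm_label,
               list(effective_kev = energy))
}

new_ct_image <- function(hu, pixel_size, arm_label, energy_meta) {
  hu <- unclass(hu)
  attr(hu, "pixel_size") <- NULL
  structure(
    list(hu = hu, pixel_size = pixel_size, arm_label = arm_label,
         energy_meta = energy_meta),
    class = "ct_image"
  )
}

#' Reconstruct a sinogram straight to Hounsfield units
#'
#' Convenience chain [fbp()] then [to_hu()] at the sinogram spectrum's
#' effective energy.
#'
#' @param sinogram A `ct_sinogram`.
#' @param filter_name FBP filter.
#' @param n_out Output grid side.
#' @param arm_label Label recorded on the image (defaults to
#'   `raw_<kvp_label>`).
#' @return A `ct_image`.
#' @export
reconstruct <- function(sinogram, filter_name = "ramp", n_out = NULL,
                        arm_label = paste0("raw_", sinogram$kvp_label)) {
  mu <- fbp(sinogram, filter_name, n_out = n_out)
  to_hu(mu, effective_energy(sinogram$spectrum), sinogram$pixel_size,
        arm_label)
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image %s: %dx%d px, %.3f cm/px, HU range [%.0f, %.0f]>\n",
              x$arm_label, nrow(x$hu), ncol(x$hu), x$pixel_size,
              min(x$hu), max(x$hu)))
  invisible(x)
}

#' Raster plot of a CT image
#'
#' @param object A `ct_image`.
#' @param window HU display window `c(center, width)`; default soft tissue
#'   (50, 350).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_image <- function(object, window = c(50, 350), ...) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(object$hu)), each = nrow(object$hu)),
    y = rep(rev(seq_len(nrow(object$hu))), ncol(object$hu)),
    hu = as.vector(object$hu)
  )
  lo <- window[1] - window[2] / 2
  hi <- window[1] + window[2] / 2
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = pmin(pmax(.data$hu, lo), hi))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "HU") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$arm_label, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
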