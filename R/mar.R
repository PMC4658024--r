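#' Segment metal from a reconstructed image
#'
#' Thresholding at `threshold_hu` followed by a morphological opening
#' (strips one-pixel streak spikes that exceed the threshold near strong
#' artefacts) and closing (fills specks), both radius 1. The default
#' 3000 HU sits above cortical bone and below any simulated metal plateau.
#' An empty mask is allowed; downstream MAR then degrades to a no-op.
#'
#' @param image A `ct_image`.
#' @param threshold_hu Segmentation threshold in HU (> 1500).
#' @return A `metal_mask`: list with `mask` (logical matrix) and
#'   `threshold_hu`.
#' @export
segment_metal <- function(image, threshold_hu = 3000) {
  if (threshold_hu <= 1500) {
    stop("threshold_hu must exceed 1500 HU", call. = FALSE)
  }
  raw <- image$hu >= threshold_hu
  mask <- raw
  if (any(raw)) {
    br <- EBImage::makeBrush(3, "box")
    cleaned <- EBImage::closing(EBImage::opening(raw * 1, br), br)
    mask <- matrix(as.numeric(cleaned) > 0.5, nrow(raw))
  }
  structure(list(mask = mask, threshold_hu = threshold_hu),
            class = "metal_mask")
}

#' Metal trace of a mask in the sinogram domain
#'
#' Forward-projects the binary mask and flags every ray whose path length
#' through metal exceeds half a pixel (the forward-projection tolerance).
#' Monotone: a superset mask yields a superset trace.
#'
#' @param mask A `metal_mask` (or logical matrix).
#' @param geometry The `ct_geometry` of the sinogram to be inpainted.
#' @param pixel_size Pixel size in cm.
#' @return Logical `n_angles x n_detectors` matrix (the inpainting domain).
#' @export
forward_trace <- function(mask, geometry, pixel_size = geometry$pixel_size) {
  m <- if (inherits(mask, "metal_mask")) mask$mask else mask
  if (!any(m)) {
    return(matrix(FALSE, geometry$n_angles, geometry$n_detectors))
  }
  pl <- radon_forward(m * 1.0, geometry$angles, geometry$n_detectors,
                      geometry$det_spacing, pixel_size, 0.5)
  pl > 0.5 * pixel_size
}

# documented fallback plateaus when a tissue class is empty
FALLBACK_PLATEAU <- c(air = -1000, soft = 40, bone = 1500)

#' Build the three-plateau prior image for normalized inpainting
#'
#' Classifies every pixel as air (`HU < t_air`), bone (`HU > t_bone`) or
#' soft tissue, sets each class to its median HU (metal pixels are excluded
#' from the medians and assigned the soft plateau), then smooths with a
#' Gaussian to avoid step discontinuities at class borders. Classification
#' runs on a median-filtered copy of the image so that thin, impulsive
#' streaks do not masquerade as bone or air in the prior (plateau medians
#' still come from the original values). The prior is what prevents the
#' sinogram interpolation from introducing new artefacts tangential to
#' high-contrast objects.
#'
#' @param image Current `ct_image`.
#' @param mask A `metal_mask`.
#' @param t_air,t_bone Class thresholds in HU (`t_air < t_bone`).
#' @param sigma_prior Gaussian smoothing sigma in px; 0 or `smooth = FALSE`
#'   skips smoothing.
#' @param smooth Apply the smoothing step (default `TRUE`).
#' @param denoise_radius Median-filter radius (px) for the classification
#'   copy; 0 disables.
#' @return A `ct_image` with arm label `"prior"`.
#' @export
build_prior <- function(image, mask, t_air = -500, t_bone = 500,
                        sigma_prior = 6, smooth = TRUE, denoise_radius = 2) {
  if (t_air >= t_bone) stop("thresholds must satisfy t_air < t_bone", call. = FALSE)
  hu <- image$hu
  m <- mask$mask
  hu_cls <- if (denoise_radius > 0) median_filter_hu(hu, denoise_radius) else hu
  air <- hu_cls < t_air
  if (any(air)) {
    # true air is connected to the image border; enclosed dark bands around
    # an implant are artefact, not anatomy, and stay soft tissue
    lab <- EBImage::bwlabel(air * 1)
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border_ids <- border_ids[border_ids > 0]
    air <- matrix(lab %in% border_ids, nrow(lab))
  }
  cls <- matrix("soft", nrow(hu), ncol(hu))
  cls[air] <- "air"
  cls[!air & hu_cls > t_bone] <- "bone"
  cls[m] <- "metal"
  plateau <- vapply(c("air", "soft", "bone"), function(k) {
    v <- hu[cls == k]
    if (length(v) == 0) {
      warning("empty ", k, " class; using fallback plateau", call. = FALSE)
      FALLBACK_PLATEAU[[k]]
    } else median(v)
  }, numeric(1))
  # sanity ranges keep a streak-contaminated class median from running away
  # across MAR cycles; the prior is a tissue model, not a measurement
  plateau[["air"]] <- min(max(plateau[["air"]], -1100), -850)
  plateau[["soft"]] <- min(max(plateau[["soft"]], -150), 250)
  plateau[["bone"]] <- min(max(plateau[["bone"]], 250), 2200)
  out <- matrix(plateau[["soft"]], nrow(hu), ncol(hu))
  out[cls == "air"] <- plateau[["air"]]
  out[cls == "bone"] <- plateau[["bone"]]
  # metal pixels already at the soft plateau by construction
  if (smooth && sigma_prior > 0) {
    out <- EBImage::gblur(out, sigma = sigma_prior)
    out <- matrix(as.numeric(out), nrow(hu))
  }
  new_ct_image(out, image$pixel_size, "prior", image$energy_meta)
}

# interpolate the values at positions `idx` of vector v from its other
# entries; rule = 2 extends flat at the ends
fill_1d <- function(v, idx) {
  known <- which(!idx)
  v[idx] <- approx(known, v[known], xout = which(idx), rule = 2)$y
  v
}

#' Normalized sinogram interpolation (NMAR)
#'
#' Divides the measured sinogram by the forward projection of the prior
#' image, linearly interpolates the normalized data across the metal trace
#' along the detector axis (views fully covered by the trace interpolate
#' along the angle axis instead), and re-multiplies by the prior
#' projection. Rays outside the trace are returned bit-identical to the
#' input.
#'
#' @param sinogram A `ct_sinogram` (log line integrals).
#' @param trace Logical trace matrix from [forward_trace()].
#' @param prior Prior `ct_image` from [build_prior()].
#' @param geometry Geometry (defaults to the sinogram's own).
#' @return A corrected `ct_sinogram`.
#' @export
nmar <- function(sinogram, trace, prior, geometry = sinogram$geometry) {
  p <- sinogram$values
  if (!any(trace)) return(sinogram)
  if (all(trace)) stop("metal too large for inpainting", call. = FALSE)
  e_eff <- effective_energy(sinogram$spectrum)
  mu_prior <- mu_water(e_eff) * (1 + prior$hu / 1000)
  mu_prior[mu_prior < 0] <- 0
  p_prior <- radon(mu_prior, geometry, sinogram$pixel_size)
  pos <- p_prior[p_prior > 0]
  eps <- if (length(pos) == 0) 1e-4 else 1e-4 * median(pos)
  denom <- p_prior + eps
  p_norm <- p / denom
  full <- rowSums(!trace) == 0
  for (a in which(!full)) {
    idx <- trace[a, ]
    if (any(idx)) p_norm[a, ] <- fill_1d(p_norm[a, ], idx)
  }
  if (any(full)) {
    for (k in seq_len(ncol(p_norm))) {
      p_norm[, k] <- fill_1d(p_norm[, k], full & trace[, k])
    }
  }
  corrected <- p_norm * denom
  # inpainted rays are surrogate metal-free measurements: keep them inside
  # the measured sinogram's range (prevents prior/normalization feedback)
  corrected <- pmin(pmax(corrected, min(p)), max(p))
  corrected[!trace] <- p[!trace]   # data fidelity outside the trace
  out <- sinogram
  out$values <- corrected
  out$noise_meta$corrected <- "nmar"
  out
}

# median filter an HU matrix (EBImage works on [0,1] grayscale)
median_filter_hu <- function(hu, radius) {
  lo <- -1024; hi <- max(hu, 3071)
  scaled <- (pmin(pmax(hu, lo), hi) - lo) / (hi - lo)
  filt <- EBImage::medianFilter(scaled, radius)
  matrix(as.numeric(filt), nrow(hu)) * (hi - lo) + lo
}

gblur_mat <- function(m, sigma) {
  matrix(as.numeric(EBImage::gblur(m, sigma = sigma)), nrow(m))
}

#' Frequency-split recombination (FSMAR)
#'
#' Keeps the low-pass band of the inpainting-corrected image everywhere,
#' but restores the high-pass band of the original image in a feathered
#' neighbourhood of the metal, preserving implant edges that pure sinogram
#' inpainting destroys. Metal pixels are re-inserted from the original.
#'
#' @param corrected Corrected `ct_image` (after NMAR + FBP).
#' @param original Uncorrected `ct_image` (same grid).
#' @param mask A `metal_mask`.
#' @param sigma_split Gaussian sigma of the low-pass split (px).
#' @param w_edge Weight of the original's high band near metal, between 0 and 1.
#' @param r_edge Dilation radius (px) of the metal neighbourhood.
#' @return A `ct_image` carrying the corrected label.
#' @export
frequency_split <- function(corrected, original, mask, sigma_split = 2,
                            w_edge = 1, r_edge = 6) {
  if (sigma_split <= 0) stop("sigma_split must be positive", call. = FALSE)
  stopifnot(all(dim(corrected$hu) == dim(original$hu)))
  lp_c <- gblur_mat(corrected$hu, sigma_split)
  hp_c <- corrected$hu - lp_c
  lp_o <- gblur_mat(original$hu, sigma_split)
  hp_o <- original$hu - lp_o
  m <- mask$mask
  if (any(m) && w_edge > 0) {
    brush <- EBImage::makeBrush(2 * r_edge + 1, "disc")
    near <- matrix(as.numeric(EBImage::dilate(m * 1, brush)) > 0.5, nrow(m))
    w <- gblur_mat(near * w_edge, r_edge / 2)
    w <- pmin(pmax(w, 0), w_edge)
  } else {
    w <- matrix(0, nrow(m), ncol(m))
  }
  hu <- lp_c + w * hp_o + (1 - w) * hp_c
  hu[m] <- original$hu[m]
  new_ct_image(hu, corrected$pixel_size, corrected$arm_label,
               corrected$energy_meta)
}

# implant density tier -> number of NMAR/FSMAR cycles
TIER_CYCLES <- c(titanium = 3, steel = 4, amalgam = 6)

#' Iterative metal artefact reduction (one kV channel)
#'
#' Reconstructs the channel, segments metal and freezes the metal trace,
#' then cycles: build a three-plateau prior from the current image,
#' normalized sinogram interpolation, FBP, frequency-split recombination
#' with the uncorrected image. Each cycle's output seeds the next prior.
#' The cycle count is tied to the anticipated implant density: 3 for
#' titanium, 4 for steel, 6 for amalgam (configurable via
#' `config$tier_cycles`). On a metal-free image the plain FBP is returned
#' unchanged and a message is emitted.
#'
#' @param sinogram A `ct_sinogram` of one kV channel.
#' @param material_tier `"titanium"`, `"steel"` or `"amalgam"`.
#' @param config Parameter list from [mar_config()].
#' @param n_out Reconstruction grid side.
#' @return A `ct_image` with `arm_label = "IMAR-channel"` and attribute
#'   `n_cycles`.
#' @export
imar <- function(sinogram, material_tier = "titanium", config = mar_config(),
                 n_out = NULL) {
  cycles <- config$tier_cycles[[material_tier]]
  if (is.null(cycles) || cycles < 3 || cycles > 6) {
    stop("material tier must map to 3..6 cycles", call. = FALSE)
  }
  e_eff <- effective_energy(sinogram$spectrum)
  mu0 <- fbp(sinogram, config$filter_name, n_out = n_out)
  original <- to_hu(mu0, e_eff, sinogram$pixel_size,
                    paste0("raw_", sinogram$kvp_label))
  mask <- segment_metal(original, config$metal_threshold)
  if (!any(mask$mask)) {
    message("no metal found; returning plain FBP")
    attr(original, "n_cycles") <- 0
    return(original)
  }
  trace <- forward_trace(mask, sinogram$geometry, sinogram$pixel_size)
  current <- original
  for (cy in seq_len(cycles)) {
    prior <- build_prior(current, mask, config$t_air, config$t_bone,
                         config$sigma_prior,
                         denoise_radius = config$prior_denoise)
    sc <- nmar(sinogram, trace, prior)
    mu_c <- fbp(sc, config$filter_name, n_out = nrow(original$hu))
    img_c <- to_hu(mu_c, e_eff, sinogram$pixel_size, "IMAR-channel")
    current <- frequency_split(img_c, original, mask, config$sigma_split,
                               config$w_edge, config$r_edge)
  }
  current$arm_label <- "IMAR-channel"
  attr(current, "n_cycles") <- cycles
  attr(current, "mask") <- mask
  current
}
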