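#' @importFrom stats approx fft median quantile rbinom rpois runif sd
#' @importFrom rlang .data
NULL

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derived per-case seed: documented rule, stays below 2^31 - 1
derive_seed <- function(master_seed, index) {
  ((master_seed %% 97561) * 20011 + 7919 * index) %% 2147483629
}

PHANTOM_KINDS <- c("hip_unilateral", "hip_bilateral", "dental", "custom")

#' Digital CT phantom bearing metal implants
#'
#' A `ct_phantom` is a square 2D grid of material labels with a physical
#' pixel size, the ground truth of every simulation. `make_phantom` draws
#' one of the study's two implant geometries:
#'
#' * **hip** (`hip_unilateral`, `hip_bilateral`): an elliptical pelvis of
#'   soft tissue with sacral and iliac bone, femoral bone heads of which one
#'   or two are replaced by a metal prosthesis head (disc diameter >= 10% of
#'   the grid), plus two small iodinated vessels;
#' * **dental**: a head-sized soft-tissue disc with a mandibular bone arc
#'   carrying 2-6 small metal implants placed pseudo-randomly from the seed,
#'   plus two iodinated vessels.
#'
#' Geometry is mildly jittered per seed so a cohort of phantoms varies.
#' Every phantom guarantees an artefact-remote soft-tissue-only patch of at
#' least 20x20 pixels for the noise ROI (stored in `$noise_roi`) and carries
#' a default scoring polygon around the implant-bearing bone (`$roi`).
#'
#' @param kind One of `"hip_unilateral"`, `"hip_bilateral"`, `"dental"`.
#' @param grid_size Grid side in pixels (>= 128).
#' @param seed Integer seed; identical arguments give identical phantoms.
#' @param pixel_size Pixel size in cm; defaults to a 40 cm field of view for
#'   hip kinds and 22 cm for dental.
#' @return A `ct_phantom`: list with `labels` (integer matrix indexing into
#'   `materials$name`), `materials` (the material table), `pixel_size`,
#'   `kind`, `seed`, `implant_material`, `metal_mask_truth` (logical
#'   matrix), `noise_roi` (list `center` = (x, y) 0-based, `radius` px) and
#'   `roi` (a [polygon_roi()]).
#' @examples
#' ph <- make_phantom("hip_unilateral", 128, seed = 1)
#' mean(ph$metal_mask_truth)
#' @export
make_phantom <- function(kind = PHANTOM_KINDS, grid_size = 256, seed = 1,
                         pixel_size = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    stop("custom phantoms are built with ct_phantom() from a label matrix",
         call. = FALSE)
  }
  if (grid_size < 128) {
    stop("grid_size must be >= 128 to place implants", call. = FALSE)
  }
  if (is.null(pixel_size)) {
    pixel_size <- if (startsWith(kind, "hip")) 40 / grid_size else 22 / grid_size
  }
  with_seed(seed, {
    if (startsWith(kind, "hip")) {
      build_hip_phantom(kind, grid_size, seed, pixel_size)
    } else {
      build_dental_phantom(grid_size, seed, pixel_size)
    }
  })
}

# coordinate grids in units of the grid side, 0-based pixel centers
unit_grids <- function(n) {
  x <- matrix(rep(0:(n - 1), each = n), n, n) / n  # column coordinate
  y <- matrix(rep(0:(n - 1), n), n, n) / n         # row coordinate
  list(x = x, y = y)
}

in_ellipse <- function(g, cx, cy, rx, ry) {
  ((g$x - cx) / rx)^2 + ((g$y - cy) / ry)^2 <= 1
}

material_codes <- function(materials) {
  stats::setNames(seq_len(nrow(materials)), materials$name)
}

new_ct_phantom <- function(labels, materials, pixel_size, kind, seed,
                           implant_material, noise_roi, roi) {
  metal_codes <- which(materials$is_metal)
  structure(
    list(labels = labels, materials = materials, pixel_size = pixel_size,
         kind = kind, seed = seed, implant_material = implant_material,
         metal_mask_truth = matrix(labels %in% metal_codes, nrow(labels)),
         noise_roi = noise_roi, roi = roi),
    class = "ct_phantom"
  )
}

#' Construct a phantom from a label matrix
#'
#' Escape hatch for custom geometries and for file round-trips.
#'
#' @param labels Integer matrix of material codes (rows of `materials`).
#' @param materials Material table, see [material_table()].
#' @param pixel_size Pixel size in cm.
#' @param kind Kind tag; defaults to `"custom"`.
#' @param seed Seed recorded for provenance.
#' @param noise_roi,roi Optional noise-ROI descriptor and scoring polygon.
#' @export
ct_phantom <- function(labels, materials = material_table(), pixel_size,
                       kind = "custom", seed = NA_integer_,
                       noise_roi = NULL, roi = NULL) {
  stopifnot(is.matrix(labels), nrow(labels) == ncol(labels), pixel_size > 0)
  new_ct_phantom(labels, materials, pixel_size, kind, seed,
                 implant_material = NA_character_,
                 noise_roi = noise_roi, roi = roi)
}

build_hip_phantom <- function(kind, n, seed, pixel_size) {
  materials <- material_table()
  code <- material_codes(materials)
  g <- unit_grids(n)
  jit <- function(s) runif(1, -s, s)

  labels <- matrix(code[["air"]], n, n)
  # pelvis
  bx <- 0.45 + jit(0.015); by <- 0.33 + jit(0.015)
  body <- in_ellipse(g, 0.5, 0.53, bx, by)
  labels[body] <- code[["soft_tissue"]]
  # sacrum + iliac wings (kept clear of the scoring polygon's annulus)
  labels[in_ellipse(g, 0.5, 0.68 + jit(0.01), 0.10, 0.065)] <- code[["bone"]]
  labels[in_ellipse(g, 0.36 + jit(0.01), 0.66, 0.055, 0.04)] <- code[["bone"]]
  labels[in_ellipse(g, 0.64 + jit(0.01), 0.66, 0.055, 0.04)] <- code[["bone"]]
  # femoral heads: bone disc, implant sides get a concentric metal head
  hipy <- 0.52 + jit(0.01)
  lx <- 0.22 + jit(0.01); rx <- 0.78 + jit(0.01)
  labels[in_ellipse(g, lx, hipy, 0.085, 0.085)] <- code[["bone"]]
  labels[in_ellipse(g, rx, hipy, 0.085, 0.085)] <- code[["bone"]]
  tier <- if (runif(1) < 0.5) "titanium" else "steel"
  r_met <- 0.055 + jit(0.005)  # diameter ~0.11 n >= 10% of grid
  labels[in_ellipse(g, lx, hipy, r_met, r_met)] <- code[[tier]]
  if (kind == "hip_bilateral") {
    labels[in_ellipse(g, rx, hipy, r_met, r_met)] <- code[[tier]]
  }
  # iodinated vessels
  labels[in_ellipse(g, 0.42, 0.38, 0.018, 0.018)] <- code[["iodine_blood"]]
  labels[in_ellipse(g, 0.58, 0.38, 0.018, 0.018)] <- code[["iodine_blood"]]

  noise_roi <- list(center = c(0.5, 0.29) * n, radius = max(10, 0.05 * n))
  # scoring polygon: soft-tissue annulus just outside the implant-bearing
  # bone, where streaks radiate; avoids crossing anatomy so the metal-free
  # trace is quiet
  roi <- regular_polygon(center = c(lx, hipy) * n, radius = 0.11 * n,
                         n_vertices = 16)
  new_ct_phantom(labels, materials, pixel_size, kind, seed, tier,
                 noise_roi, roi)
}

build_dental_phantom <- function(n, seed, pixel_size) {
  materials <- material_table()
  code <- material_codes(materials)
  g <- unit_grids(n)
  jit <- function(s) runif(1, -s, s)

  labels <- matrix(code[["air"]], n, n)
  labels[in_ellipse(g, 0.5, 0.5, 0.40 + jit(0.01), 0.40 + jit(0.01))] <-
    code[["soft_tissue"]]
  # mandibular arc: annulus band opening towards the top of the image
  r0 <- 0.295 + jit(0.01)
  dx <- g$x - 0.5; dy <- g$y - 0.5
  rr <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)                       # pi/2 points down the image
  arc <- abs(rr - r0) <= 0.035 & abs(phi - pi / 2) <= 1.05
  labels[arc] <- code[["bone"]]
  # 2-6 crown-sized amalgam implants on the arc, minimum angular separation
  k <- sample(2:6, 1)
  ang <- numeric(0)
  while (length(ang) < k) {
    cand <- runif(1, pi / 2 - 0.95, pi / 2 + 0.95)
    if (all(abs(cand - ang) > 0.22)) ang <- c(ang, cand)
  }
  r_tooth <- max(3 / n, 0.024)
  for (a in ang) {
    labels[in_ellipse(g, 0.5 + r0 * cos(a), 0.5 + r0 * sin(a),
                      r_tooth, r_tooth)] <- code[["amalgam"]]
  }
  # iodinated vessels (carotid-like), well away from the jaw
  labels[in_ellipse(g, 0.30, 0.32, 0.018, 0.018)] <- code[["iodine_blood"]]
  labels[in_ellipse(g, 0.70, 0.32, 0.018, 0.018)] <- code[["iodine_blood"]]

  noise_roi <- list(center = c(0.5, 0.42) * n, radius = max(10, 0.05 * n))
  # scoring polygon: soft-tissue ring between the jaw arc and the skin,
  # crossed by streaks radiating outward from the dental hardware
  roi <- regular_polygon(center = c(0.5, 0.5) * n, radius = 0.365 * n,
                         n_vertices = 16)
  new_ct_phantom(labels, materials, pixel_size, "dental", seed, "amalgam",
                 noise_roi, roi)
}

#' Replace metal by a surrogate tissue
#'
#' Returns the metal-free control of a phantom: every metal pixel is
#' relabelled (bone by default), everything else untouched. Used to measure
#' how much artefact the implant itself adds.
#'
#' @param phantom A `ct_phantom`.
#' @param replacement Material name to substitute for metal.
#' @export
strip_metal <- function(phantom, replacement = "bone") {
  code <- material_codes(phantom$materials)
  labels <- phantom$labels
  labels[phantom$metal_mask_truth] <- code[[replacement]]
  out <- new_ct_phantom(labels, phantom$materials, phantom$pixel_size,
                        phantom$kind, phantom$seed, NA_character_,
                        phantom$noise_roi, phantom$roi)
  out
}

#' Simulate a cohort of phantoms
#'
#' Reproduces the study's strata: `n_hip` hip cases (roughly one in nine
#' bilateral, the remainder unilateral) and `n_dental` dental cases. Each
#' phantom's seed is derived from `master_seed` and the case index by the
#' documented rule `((master %% 97561) * 20011 + 7919 * i) %% 2147483629`,
#' so cohorts are reproducible element-wise.
#'
#' @param n_hip,n_dental Number of cases per stratum (>= 0).
#' @param grid_size Grid side in pixels.
#' @param master_seed Integer master seed.
#' @return A list of `ct_phantom` objects, hip cases first; each carries a
#'   `case_id` field `"hip_01"`, ..., `"dental_01"`, ...
#' @export
make_cohort <- function(n_hip, n_dental, grid_size = 256, master_seed = 1) {
  stopifnot(n_hip >= 0, n_dental >= 0)
  out <- list()
  idx <- 0
  for (i in seq_len(n_hip)) {
    idx <- idx + 1
    kind <- if (i %% 9 == 0) "hip_bilateral" else "hip_unilateral"
    ph <- make_phantom(kind, grid_size, seed = derive_seed(master_seed, idx))
    ph$case_id <- sprintf("hip_%02d", i)
    ph$stratum <- "hip"
    out[[idx]] <- ph
  }
  for (i in seq_len(n_dental)) {
    idx <- idx + 1
    ph <- make_phantom("dental", grid_size, seed = derive_seed(master_seed, idx))
    ph$case_id <- sprintf("dental_%02d", i)
    ph$stratum <- "dental"
    out[[idx]] <- ph
  }
  out
}

#' Count connected metal components of a phantom
#'
#' @param phantom A `ct_phantom`.
#' @return Number of 4-connected components in the truth metal mask.
#' @export
metal_components <- function(phantom) {
  lab <- EBImage::bwlabel(phantom$metal_mask_truth * 1)
  max(lab)
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom %s: %dx%d px, %.3f cm/px, metal %s (%.2f%% of grid)>\n",
              x$kind, nrow(x$labels), ncol(x$labels), x$pixel_size,
              x$implant_material, 100 * mean(x$metal_mask_truth)))
  invisible(x)
}

#' Per-material binary masks of a phantom
#'
#' @param phantom A `ct_phantom`.
#' @return Named list of logical matrices, one per material present.
#' @export
material_masks <- function(phantom) {
  present <- sort(unique(as.vector(phantom$labels)))
  masks <- lapply(present, function(k) phantom$labels == k)
  names(masks) <- phantom$materials$name[present]
  masks
}
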