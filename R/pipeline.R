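#' Pipeline configuration
#'
#' One place for every tunable of the simulation and MAR chain. Defaults
#' are the package's study conditions; any entry can be overridden by
#' name.
#'
#' * `n_angles` 180 views over half a turn; `n_bins` 24 spectrum bins.
#' * `n0_low` / `n0_high`: source photons per ray for the 100 kV and
#'   tin-filtered 140 kV channels (1e7 / 2e7), chosen so artefact-remote
#'   soft tissue shows clinically realistic noise (roughly 10 HU) while
#'   rays through the implant starve completely.
#' * `metal_threshold` 3000 HU; prior thresholds `t_air` -500 HU,
#'   `t_bone` 500 HU, `sigma_prior` 6 px, `prior_denoise` 2 px median
#'   filter before tissue classification.
#' * FSMAR: `sigma_split` 2 px, `r_edge` 6 px, `w_edge` 1.
#' * `tier_cycles`: titanium 3, steel 4, amalgam 6 NMAR/FSMAR cycles.
#' * Dual energy: mixing weight `mix_w` 0.5, `vmi_kev` 130 keV target,
#'   `ref_kev` 70 keV reference, `sigma_noise` 2 px, `lambda` 1.
#' * `n_slices` 1: each cohort case is scored on one noise realization
#'   (phantoms are single slices; multi-slice averaging is available
#'   through [score_case()]).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters.
#' @export
mar_config <- function(...) {
  config <- list(
    n_angles = 180, n_bins = 24,
    n0_low = 1e7, n0_high = 2e7,
    filter_name = "ramp",
    metal_threshold = 3000,
    t_air = -500, t_bone = 500, sigma_prior = 6, prior_denoise = 2,
    sigma_split = 2, r_edge = 6, w_edge = 1,
    tier_cycles = TIER_CYCLES,
    material_tier = "titanium",
    mix_w = 0.5, vmi_kev = 130, ref_kev = 70,
    sigma_noise = 2, lambda = 1,
    n_slices = 1
  )
  dots <- list(...)
  stopifnot(all(nzchar(names(dots))))
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown) > 0) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config[names(dots)] <- dots
  config
}

#' Acquire the dual-energy sinogram pair of a phantom
#'
#' Projects the phantom once (path lengths are energy independent) and
#' acquires both kV channels with independent noise seeds derived from
#' `seed`.
#'
#' @param phantom A `ct_phantom`.
#' @param config Configuration from [mar_config()].
#' @param seed Integer seed; `NULL` gives a noiseless pair.
#' @param paths Optional precomputed [project()] output.
#' @return List with `ct_sinogram` elements `low` and `high`.
#' @export
acquire_pair <- function(phantom, config = mar_config(), seed = 1,
                         paths = NULL) {
  geometry <- default_geometry(phantom, config$n_angles)
  if (is.null(paths)) paths <- project(phantom, geometry)
  spec_lo <- make_spectrum("kv100", config$n_bins)
  spec_hi <- make_spectrum("kv140Sn", config$n_bins)
  if (is.null(seed)) {
    list(low = acquire(phantom, geometry, spec_lo, paths = paths),
         high = acquire(phantom, geometry, spec_hi, paths = paths))
  } else {
    list(low = acquire(phantom, geometry, spec_lo, n0 = config$n0_low,
                       seed = derive_seed(seed, 1), paths = paths),
         high = acquire(phantom, geometry, spec_hi, n0 = config$n0_high,
                        seed = derive_seed(seed, 2), paths = paths))
  }
}

#' Simulate, reconstruct and score one case
#'
#' Runs the full chain for one phantom: dual-energy acquisition, the four
#' reconstruction arms, and polygon-trace Fourier scoring with the
#' phantom's own ROI. With `config$n_slices > 1`, additional noise
#' realizations of the same phantom stand in for neighbouring slices and
#' their scores are averaged.
#'
#' @param phantom A `ct_phantom` (its `implant_material` selects the IMAR
#'   cycle count).
#' @param config Configuration from [mar_config()].
#' @param seed Integer seed for the acquisition noise.
#' @param keep_images Also return the arm images of the first slice.
#' @return A tibble of case scores (one row per arm, see [score_case()]),
#'   with a `stratum` column; when `keep_images` is set, the images are
#'   attached as attribute `"images"`.
#' @export
run_case <- function(phantom, config = mar_config(), seed = 1,
                     keep_images = FALSE) {
  if (!is.na(phantom$implant_material)) {
    config$material_tier <- phantom$implant_material
  }
  geometry <- default_geometry(phantom, config$n_angles)
  paths <- project(phantom, geometry)
  n_out <- nrow(phantom$labels)
  slices <- lapply(seq_len(config$n_slices), function(s) {
    pair <- acquire_pair(phantom, config, seed = derive_seed(seed, 100 + s),
                         paths = paths)
    suppressMessages(run_arms(pair, config, n_out = n_out))
  })
  images <- lapply(ARM_LABELS, function(a) lapply(slices, `[[`, a))
  names(images) <- ARM_LABELS
  scores <- score_case(images, phantom$roi, n_slices = config$n_slices,
                       case_id = phantom$case_id %||% "case")
  scores$stratum <- phantom$stratum %||% strsplit(phantom$kind, "_")[[1]][1]
  if (keep_images) {
    attr(scores, "images") <- lapply(images, `[[`, 1)
  }
  scores
}

#' Run the full cohort pipeline
#'
#' Simulates the study cohort (hip and dental strata), runs the four arms
#' on every case, scores them, and compares arms per stratum. This is the
#' package's top-level entry point.
#'
#' @param n_hip,n_dental Cases per stratum.
#' @param grid_size Phantom grid side in pixels.
#' @param seed Master seed for phantom generation and acquisition noise.
#' @param config Configuration from [mar_config()].
#' @param progress Emit a message per case.
#' @return A list of class `cohort_result`: `scores` (tibble, one row per
#'   case x arm), `comparisons` (named list of [compare_arms()] results
#'   per stratum), `config` and `seed`.
#' @export
run_cohort <- function(n_hip = 20, n_dental = 30, grid_size = 256,
                       seed = 1, config = mar_config(), progress = FALSE) {
  cohort <- make_cohort(n_hip, n_dental, grid_size, master_seed = seed)
  scores <- purrr::imap(cohort, function(ph, i) {
    if (progress) message("case ", ph$case_id)
    run_case(ph, config, seed = derive_seed(seed, 1000 + i))
  })
  scores <- dplyr::bind_rows(scores)
  strata <- unique(scores$stratum)
  comparisons <- lapply(strata, function(s) compare_arms(scores, s))
  names(comparisons) <- strata
  structure(list(scores = scores, comparisons = comparisons,
                 config = config, seed = seed),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result: %d cases, seed %d>\n",
              length(unique(x$scores$case_id)), x$seed))
  for (s in names(x$comparisons)) {
    cat("\n")
    print(x$comparisons[[s]])
  }
  invisible(x)
}
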