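#' Write / read a phantom as a label image plus JSON sidecar
#'
#' The label grid goes to a grayscale PNG (`<path>.png`, code = label
#' index / 255; the material table never exceeds 255 entries) and the
#' metadata — pixel size, kind, seed, implant material, noise ROI, scoring
#' polygon and the material table — to `<path>.json`.
#'
#' @param phantom A `ct_phantom`.
#' @param path Base path without extension.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  png::writePNG(phantom$labels / 255, paste0(path, ".png"))
  meta <- list(
    pixel_size = phantom$pixel_size, kind = phantom$kind,
    seed = phantom$seed, implant_material = phantom$implant_material,
    case_id = phantom$case_id, stratum = phantom$stratum,
    noise_roi = phantom$noise_roi,
    roi_vertices = unname(phantom$roi$vertices),
    roi_n_samples = phantom$roi$n_samples,
    materials = phantom$materials
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  labels <- round(png::readPNG(paste0(path, ".png")) * 255)
  storage.mode(labels) <- "integer"
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  materials <- tibble::as_tibble(meta$materials)
  roi <- polygon_roi(meta$roi_vertices, n_samples = meta$roi_n_samples)
  ph <- new_ct_phantom(labels, materials, meta$pixel_size, meta$kind,
                       meta$seed %||% NA_integer_,
                       meta$implant_material %||% NA_character_,
                       list(center = unlist(meta$noise_roi$center),
                            radius = meta$noise_roi$radius),
                       roi)
  ph$case_id <- meta$case_id
  ph$stratum <- meta$stratum
  ph
}

#' Write / read a reconstructed image as 32-bit float TIFF plus sidecar
#'
#' HU values go to `<path>.tiff` (32-bit float, affinely mapped onto the unit range;
#' the HU range is recorded in the sidecar), pixel size, arm label and
#' energy metadata to `<path>.json`.
#'
#' @param image A `ct_image`.
#' @param path Base path without extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  lo <- min(image$hu)
  hi <- max(image$hu)
  span <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((image$hu - lo) / span, paste0(path, ".tiff"),
                  bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size = image$pixel_size, arm_label = image$arm_label,
         energy_meta = image$energy_meta, hu_min = lo, hu_span = span),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  scaled <- tiff::readTIFF(paste0(path, ".tiff"))
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  hu <- scaled * meta$hu_span + meta$hu_min
  new_ct_image(hu, meta$pixel_size, meta$arm_label, meta$energy_meta)
}

#' Read / write ratings tables
#'
#' CSV with columns `case_id`, `stratum`, `arm`, `reader1`, `reader2`
#' (and optionally `endpoint`), compatible with hand-transcribed reader
#' sheets. Scores must be integral in 0..4.
#'
#' @param file CSV path.
#' @return A ratings tibble.
#' @export
read_ratings <- function(file) {
  df <- tibble::as_tibble(utils::read.csv(file))
  stopifnot(all(c("case_id", "reader1", "reader2") %in% names(df)))
  for (col in c("reader1", "reader2")) {
    v <- df[[col]]
    if (any(v != round(v)) || any(v < 0 | v > 4)) {
      stop(col, " must hold integral Likert scores in 0..4", call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  df
}

#' @rdname read_ratings
#' @param ratings A ratings tibble.
#' @export
write_ratings <- function(ratings, file) {
  utils::write.csv(ratings, file, row.names = FALSE)
  invisible(file)
}
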