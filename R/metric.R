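#' Closed polygon region of interest
#'
#' Vertex chain in 0-based pixel coordinates (x = column, y = row),
#' implicitly closed. The scoring trace samples the polygon line at
#' `n_samples` equally spaced arc-length positions, so band indices of the
#' Fourier spectrum are comparable across cases regardless of polygon
#' perimeter.
#'
#' @param vertices Two-column matrix or data frame of (x, y) vertices
#'   (>= 3, non-self-intersecting).
#' @param case_id Optional case identifier.
#' @param n_samples Number of trace samples; a power of two >= 64.
#' @return A `polygon_roi` object.
#' @export
polygon_roi <- function(vertices, case_id = NULL, n_samples = 256) {
  v <- unname(as.matrix(vertices))
  dimnames(v) <- NULL
  storage.mode(v) <- "double"
  if (nrow(v) < 3 || ncol(v) != 2) {
    stop("need at least 3 (x, y) vertices", call. = FALSE)
  }
  if (n_samples < 64 || bitwAnd(n_samples, n_samples - 1L) != 0) {
    stop("n_samples must be a power of two >= 64", call. = FALSE)
  }
  if (polygon_self_intersects(v)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  structure(list(vertices = v, case_id = case_id, n_samples = n_samples),
            class = "polygon_roi")
}

# proper-crossing test between non-adjacent edges
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

#' Regular polygon helper
#'
#' @param center (x, y) center in 0-based pixel coordinates.
#' @param radius Circumradius in pixels.
#' @param n_vertices Number of vertices.
#' @param n_samples Trace samples, see [polygon_roi()].
#' @export
regular_polygon <- function(center, radius, n_vertices = 16,
                            n_samples = 256) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[seq_len(n_vertices)]
  polygon_roi(cbind(center[1] + radius * cos(th),
                    center[2] + radius * sin(th)),
              n_samples = n_samples)
}

#' Elliptic polygon helper
#'
#' @inheritParams regular_polygon
#' @param rx,ry Semi-axes in pixels.
#' @export
elliptic_polygon <- function(center, rx, ry, n_vertices = 16,
                             n_samples = 256) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[seq_len(n_vertices)]
  polygon_roi(cbind(center[1] + rx * cos(th), center[2] + ry * sin(th)),
              n_samples = n_samples)
}

#' Read / write polygon files
#'
#' JSON polygons are a list of `[x, y]` pairs in 0-based pixel coordinates
#' (x = column); CSV files need columns `x` and `y`.
#'
#' @param file Path to a `.json` or `.csv` polygon file.
#' @param n_samples Trace samples for the resulting ROI.
#' @return A `polygon_roi`.
#' @export
read_polygon <- function(file, n_samples = 256) {
  if (grepl("\\.csv$", file, ignore.case = TRUE)) {
    df <- utils::read.csv(file)
    v <- as.matrix(df[, c("x", "y")])
  } else {
    v <- jsonlite::fromJSON(file)
    if (!is.matrix(v)) v <- do.call(rbind, v)
  }
  polygon_roi(v, n_samples = n_samples)
}

#' @rdname read_polygon
#' @param roi A `polygon_roi` to write (JSON).
#' @export
write_polygon <- function(roi, file) {
  jsonlite::write_json(unname(roi$vertices), file, digits = NA)
  invisible(file)
}

# bilinear read of matrix `m` at 0-based (x = col, y = row) positions
sample_bilinear <- function(m, x, y) {
  n_r <- nrow(m); n_c <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x0 <- pmin(pmax(x0, 0), n_c - 2)
  y0 <- pmin(pmax(y0, 0), n_r - 2)
  i <- y0 + 1; j <- x0 + 1
  (1 - fy) * ((1 - fx) * m[cbind(i, j)] + fx * m[cbind(i, j + 1)]) +
    fy * ((1 - fx) * m[cbind(i + 1, j)] + fx * m[cbind(i + 1, j + 1)])
}

#' Sample HU values along a polygon trace
#'
#' Parameterizes the closed polyline by arc length, samples `n_samples`
#' equally spaced points starting at the first vertex and following the
#' vertex order, and reads HU by bilinear (or nearest-neighbour)
#' interpolation. The same ROI object propagated to every arm guarantees
#' index-for-index alignment of the traces.
#'
#' @param image A `ct_image`.
#' @param roi A `polygon_roi` lying inside the image bounds.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return Numeric vector of length `roi$n_samples`.
#' @export
trace_polygon <- function(image, roi,
                          interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  hu <- image$hu
  v <- roi$vertices
  out_of_bounds <- v[, 1] < 0 | v[, 1] > ncol(hu) - 1 |
    v[, 2] < 0 | v[, 2] > nrow(hu) - 1
  if (any(out_of_bounds)) {
    stop("polygon exits image at vertex index ",
         paste(which(out_of_bounds), collapse = ", "), call. = FALSE)
  }
  n <- nrow(v)
  nxt <- c(2:n, 1)
  edge_len <- sqrt(rowSums((v[nxt, , drop = FALSE] - v)^2))
  cum <- c(0, cumsum(edge_len))
  total <- cum[n + 1]
  s <- (seq_len(roi$n_samples) - 1) / roi$n_samples * total
  e <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[e]) / edge_len[e]
  px <- v[e, 1] + frac * (v[nxt[e], 1] - v[e, 1])
  py <- v[e, 2] + frac * (v[nxt[e], 2] - v[e, 2])
  if (interpolation == "nearest") {
    hu[cbind(round(py) + 1, round(px) + 1)]
  } else {
    sample_bilinear(hu, px, py)
  }
}

STREAK_BANDS <- list(`1-2` = 1:2, `3-4` = 3:4, `5-8` = 5:8, `9-16` = 9:16)

#' Fourier streak spectrum of a polygon trace
#'
#' One-sided unscaled DFT magnitudes
#' \eqn{|F_k| = |\sum_t x_t e^{-2\pi i k t / N}|} for k = 0..N/2 (no 1/N
#' factor). Streak artefacts crossing the polygon concentrate in the low
#' coefficients; image noise sits at high k. Band sums follow the
#' grouping k in {1,2}, {3,4}, {5..8}, {9..16}; the headline score
#' `total_low` sums k = 1..16. The DC term (mean HU) is excluded from all
#' scores.
#'
#' @param sequence Numeric trace of length >= 64, a power of two.
#' @return A `streak_spectrum`: list with `amplitudes` (k = 0..N/2),
#'   `band_sums` (named numeric), `total_low` and `n`.
#' @export
streak_spectrum <- function(sequence) {
  n <- length(sequence)
  if (n < 64 || bitwAnd(n, n - 1L) != 0) {
    stop("sequence length must be a power of two >= 64", call. = FALSE)
  }
  if (any(!is.finite(sequence))) stop("non-finite trace values", call. = FALSE)
  amps <- Mod(fft(sequence))[seq_len(n / 2 + 1)]  # k = 0..N/2
  band_sums <- vapply(STREAK_BANDS, function(k) sum(amps[k + 1]), numeric(1))
  structure(
    list(amplitudes = amps, band_sums = band_sums,
         total_low = sum(amps[2:17]), n = n),
    class = "streak_spectrum"
  )
}

#' @export
print.streak_spectrum <- function(x, ...) {
  cat(sprintf("<streak_spectrum N=%d: total_low %.1f | bands %s>\n", x$n,
              x$total_low,
              paste(sprintf("%s=%.1f", names(x$band_sums), x$band_sums),
                    collapse = " ")))
  invisible(x)
}

streak_score <- function(image, roi) {
  streak_spectrum(trace_polygon(image, roi))$total_low
}

#' Score a case across arms and slices
#'
#' Applies the identical polygon to every arm and slice (the propagation
#' contract: the ROI is never re-derived per arm), computes the
#' low-frequency amplitude sum per slice, and averages across slices.
#'
#' @param images Named list: arm label -> `ct_image` or list of slice
#'   `ct_image`s.
#' @param roi A `polygon_roi` shared by all arms.
#' @param n_slices Expected slices per arm (default 5); must match the
#'   supplied lists.
#' @param case_id Case identifier recorded in the output.
#' @return A tibble with one row per arm: `case_id`, `arm`, `mean_score`,
#'   band-sum means (`band_1_2`, ...), and `per_slice_scores`
#'   (list-column).
#' @export
score_case <- function(images, roi, n_slices = 5, case_id = NULL) {
  if (n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
  rows <- lapply(names(images), function(arm) {
    slices <- images[[arm]]
    if (inherits(slices, "ct_image")) slices <- list(slices)
    if (length(slices) != n_slices) {
      stop("arm ", arm, " has ", length(slices), " slices, expected ",
           n_slices, call. = FALSE)
    }
    specs <- lapply(slices, function(img) {
      streak_spectrum(trace_polygon(img, roi))
    })
    scores <- vapply(specs, function(s) s$total_low, numeric(1))
    bands <- rowMeans(vapply(specs, function(s) s$band_sums,
                             numeric(length(STREAK_BANDS))))
    tibble::tibble(
      case_id = case_id %||% roi$case_id %||% NA_character_,
      arm = arm, mean_score = mean(scores),
      band_1_2 = bands[[1]], band_3_4 = bands[[2]],
      band_5_8 = bands[[3]], band_9_16 = bands[[4]],
      per_slice_scores = list(scores)
    )
  })
  dplyr::bind_rows(rows)
}

#' Noise measurement in a circular soft-tissue ROI
#'
#' Population standard deviation of HU over pixels within `radius` of
#' `center`, intended for the phantom's guaranteed artefact-remote
#' soft-tissue patch.
#'
#' @param image A `ct_image`.
#' @param center (x, y) in 0-based pixel coordinates.
#' @param radius Radius in pixels.
#' @return Standard deviation in HU.
#' @export
noise_roi <- function(image, center, radius) {
  hu <- image$hu
  n_r <- nrow(hu); n_c <- ncol(hu)
  if (center[1] - radius < 0 || center[1] + radius > n_c - 1 ||
      center[2] - radius < 0 || center[2] + radius > n_r - 1) {
    stop("ROI circle exits the image", call. = FALSE)
  }
  x <- matrix(rep(0:(n_c - 1), each = n_r), n_r, n_c)
  y <- matrix(rep(0:(n_r - 1), n_c), n_r, n_c)
  inside <- (x - center[1])^2 + (y - center[2])^2 <= radius^2
  v <- hu[inside]
  sqrt(mean((v - mean(v))^2))
}

#' Percent change of an arm's streak score against the uncorrected arm
#'
#' @param score_arm Streak score of the corrected arm.
#' @param score_nomar Streak score of the NOMAR baseline (> 0).
#' @return Signed percent change; negative values are reductions.
#' @examples
#' percent_reduction(32359, 137035)  # -76.39
#' @export
percent_reduction <- function(score_arm, score_nomar) {
  if (any(score_nomar <= 0)) stop("baseline score must be positive", call. = FALSE)
  100 * (score_arm - score_nomar) / score_nomar
}
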