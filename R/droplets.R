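#' Bright-field image container
#'
#' Wraps a 2-D integer intensity matrix with the pixel calibration and
#' acquisition metadata needed for droplet quantification.
#'
#' @param pixels Numeric matrix of intensities (rows x columns, at
#'   least 16 x 16), non-negative and within the declared bit depth.
#' @param pixel_size_um Physical pixel size, um per pixel (> 0).
#' @param bit_depth Camera bit depth (8, 12 or 16).
#' @param condition,replicate Optional labels carried into results.
#' @return An object of class `brightfield_image`.
#' @examples
#' img <- brightfield_image(matrix(2000, 32, 32), pixel_size_um = 0.5)
#' @export
brightfield_image <- function(pixels, pixel_size_um, bit_depth = 12,
                              condition = NA_character_,
                              replicate = NA_integer_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 16 || ncol(pixels) < 16) {
    rlang::abort("Image must be at least 16 x 16 pixels.")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    rlang::abort("`pixel_size_um` must be a single positive number.")
  }
  if (!bit_depth %in% c(8, 12, 16)) {
    rlang::abort("`bit_depth` must be 8, 12 or 16.")
  }
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxv)) {
    rlang::abort("Intensities must lie within the declared bit depth.")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         bit_depth = bit_depth, condition = condition,
         replicate = replicate),
    class = "brightfield_image"
  )
}

#' @export
print.brightfield_image <- function(x, ...) {
  cat(sprintf("<brightfield_image> %d x %d px, %.3g um/px, %d-bit\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$bit_depth))
  invisible(x)
}

#' Read a bright-field image from TIFF or PNG
#'
#' Reads the first plane of a TIFF (8/12-in-16/16-bit) or PNG file and
#' attaches the pixel calibration. Multi-channel images are averaged to
#' one intensity plane.
#'
#' @param path Image path (`.tif`, `.tiff` or `.png`).
#' @inheritParams brightfield_image
#' @return A [brightfield_image()].
#' @export
read_brightfield <- function(path, pixel_size_um, bit_depth = 12,
                             condition = NA_character_,
                             replicate = NA_integer_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path, as.is = TRUE),
    "png" = png::readPNG(path) * (2^bit_depth - 1),
    rlang::abort("Unsupported image format (use TIFF or PNG).")
  )
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  brightfield_image(round(px), pixel_size_um, bit_depth,
                    condition, replicate)
}

#' Intensity threshold from a buffer blank image
#'
#' The segmentation threshold is the arithmetic mean intensity of an
#' image of plain buffer: droplets settle darker than this background.
#' An optional `offset_sd` subtracts a multiple of the buffer standard
#' deviation (`mean - k * sd`), which suppresses the speckle of
#' background pixels fluctuating below their own mean in noisy images.
#'
#' @param buffer_image A [brightfield_image()] of buffer only.
#' @param offset_sd Multiple k of the buffer SD to subtract (default 0:
#'   plain mean).
#' @return Threshold in intensity units. Warns if the buffer is
#'   saturated.
#' @examples
#' buf <- brightfield_image(matrix(2000, 32, 32), pixel_size_um = 0.5)
#' buffer_threshold(buf)
#' @export
buffer_threshold <- function(buffer_image, offset_sd = 0) {
  stopifnot(inherits(buffer_image, "brightfield_image"), offset_sd >= 0)
  px <- buffer_image$pixels
  if (length(px) == 0) rlang::abort("Empty buffer image.")
  if (all(px == 2^buffer_image$bit_depth - 1)) {
    rlang::warn("Buffer image is saturated at the bit-depth maximum.")
  }
  mean(px) - offset_sd * stats::sd(as.numeric(px))
}

# Connected-component labelling of a logical mask with 4- or
# 8-connectivity, via graph components over adjacent foreground pixels.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask),
            connectivity %in% c(4, 8))
  idx <- which(mask)
  if (length(idx) == 0) {
    return(list(labels = integer(0), rows = integer(0), cols = integer(0)))
  }
  nr <- nrow(mask); nc <- ncol(mask)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) {
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  }
  edges <- integer(0)
  for (off in offsets) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- integer(length(idx))
    nb[ok] <- id[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(which(hit), nb[hit]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  list(labels = as.integer(memb), rows = r, cols = cc)
}

#' Segment droplets and measure region shape
#'
#' Classifies pixels strictly below the threshold as droplet (droplets
#' image darker than the buffer background), labels connected
#' components under the requested connectivity, and measures each
#' region: pixel count, area (um^2), centroid, eccentricity of the
#' equivalent (same-second-moments) ellipse, equivalent diameter
#' `2 * sqrt(area / pi)` in um, and whether the region touches the
#' image border. The mask, regions and downstream coverage are
#' invariant under any strictly increasing affine rescaling applied to
#' both image and threshold.
#'
#' @param image A [brightfield_image()] (its `pixel_size_um` calibrates
#'   the um-based measurements).
#' @param threshold Intensity threshold, e.g. from [buffer_threshold()].
#' @param connectivity 4 or 8 (default 8: diagonal pixel bridges merge).
#' @return A tibble with one row per region: `label`, `n_pixels`,
#'   `area_um2`, `eccentricity`, `equiv_diameter_um`, `centroid_row`,
#'   `centroid_col`, `touches_border`. The image dimensions and
#'   threshold are attached as attributes for provenance checking.
#' @examples
#' img <- brightfield_image(matrix(2000, 64, 64), pixel_size_um = 0.5)
#' segment_droplets(img, threshold = 1000) # empty: nothing darker
#' @export
segment_droplets <- function(image, threshold, connectivity = 8) {
  stopifnot(inherits(image, "brightfield_image"))
  if (is.null(image$pixel_size_um) || is.na(image$pixel_size_um)) {
    rlang::abort("Pixel size missing: um-based filters are undefined.")
  }
  mask <- image$pixels < threshold
  lab <- label_components(mask, connectivity)
  px_um2 <- image$pixel_size_um^2
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (length(lab$labels) == 0) {
    out <- tibble::tibble(
      label = integer(0), n_pixels = integer(0), area_um2 = numeric(0),
      eccentricity = numeric(0), equiv_diameter_um = numeric(0),
      centroid_row = numeric(0), centroid_col = numeric(0),
      touches_border = logical(0)
    )
  } else {
    d <- tibble::tibble(label = lab$labels, r = lab$rows, c = lab$cols)
    out <- d %>%
      dplyr::group_by(.data$label) %>%
      dplyr::summarise(
        n_pixels = dplyr::n(),
        centroid_row = mean(.data$r),
        centroid_col = mean(.data$c),
        eccentricity = region_eccentricity(.data$r, .data$c),
        touches_border = any(.data$r == 1 | .data$r == nr |
                               .data$c == 1 | .data$c == nc),
        .groups = "drop"
      ) %>%
      dplyr::mutate(
        area_um2 = .data$n_pixels * px_um2,
        equiv_diameter_um = 2 * sqrt(.data$area_um2 / pi)
      ) %>%
      dplyr::select("label", "n_pixels", "area_um2", "eccentricity",
                    "equiv_diameter_um", "centroid_row", "centroid_col",
                    "touches_border")
  }
  attr(out, "image_dim") <- c(nr, nc)
  attr(out, "threshold") <- threshold
  attr(out, "pixel_size_um") <- image$pixel_size_um
  out
}

# Eccentricity of the ellipse with the same central second moments as
# the pixel set: sqrt(1 - lambda_min / lambda_max).
region_eccentricity <- function(r, c) {
  n <- length(r)
  if (n < 2) return(0)
  mu20 <- mean((r - mean(r))^2)
  mu02 <- mean((c - mean(c))^2)
  mu11 <- mean((r - mean(r)) * (c - mean(c)))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Apply the droplet shape filters
#'
#' Keeps regions that look like settled droplets: eccentricity at most
#' `max_eccentricity` AND equivalent diameter at least
#' `min_diameter_um`. Elongated regions (eccentricity above 0.9) and
#' sub-micrometre specks are filtered out as false readings. The
#' partition is exhaustive and exclusive.
#'
#' @param regions Region tibble from [segment_droplets()].
#' @param max_eccentricity Maximum eccentricity kept (default 0.9).
#' @param min_diameter_um Minimum equivalent diameter kept, um
#'   (default 1).
#' @return The region tibble with a logical `kept` column (attributes
#'   preserved).
#' @examples
#' img <- brightfield_image(matrix(2000, 64, 64), pixel_size_um = 0.5)
#' filter_droplets(segment_droplets(img, 1000))
#' @export
filter_droplets <- function(regions, max_eccentricity = 0.9,
                            min_diameter_um = 1) {
  stopifnot(is.data.frame(regions),
            max_eccentricity >= 0, max_eccentricity <= 1,
            min_diameter_um > 0)
  at <- attributes(regions)
  out <- dplyr::mutate(
    regions,
    kept = .data$eccentricity <= max_eccentricity &
      .data$equiv_diameter_um >= min_diameter_um
  )
  for (a in c("image_dim", "threshold", "pixel_size_um")) {
    attr(out, a) <- at[[a]]
  }
  out
}

#' Percent droplet coverage of an image
#'
#' The coverage statistic: 100 times the summed pixel area of the kept
#' droplet regions divided by the total pixel area of the image. The
#' regions must derive from the supplied image (checked via the
#' dimensions recorded at segmentation).
#'
#' @param regions Filtered region tibble from [filter_droplets()] (a
#'   tibble without a `kept` column is treated as all kept).
#' @param image The [brightfield_image()] the regions came from.
#' @return A one-row tibble: `percent_coverage`, `n_kept`,
#'   `n_filtered`, `threshold`, `condition`, `replicate`.
#' @examples
#' img <- brightfield_image(matrix(2000, 64, 64), pixel_size_um = 0.5)
#' droplet_coverage(filter_droplets(segment_droplets(img, 1000)), img)
#' @export
droplet_coverage <- function(regions, image) {
  stopifnot(is.data.frame(regions), inherits(image, "brightfield_image"))
  dims <- attr(regions, "image_dim")
  if (!is.null(dims) && !identical(dims, dim(image$pixels))) {
    rlang::abort("Regions were not measured on this image (dimension mismatch).")
  }
  kept <- if ("kept" %in% names(regions)) regions$kept else
    rep(TRUE, nrow(regions))
  total_px <- prod(dim(image$pixels))
  tibble::tibble(
    percent_coverage = 100 * sum(regions$n_pixels[kept]) / total_px,
    n_kept = sum(kept),
    n_filtered = sum(!kept),
    threshold = attr(regions, "threshold") %||% NA_real_,
    condition = image$condition,
    replicate = image$replicate
  )
}

#' One-shot droplet quantification pipeline
#'
#' Threshold (from a buffer image or explicit value), segment, filter
#' and compute percent coverage for one image.
#'
#' @param image A [brightfield_image()].
#' @param buffer_image Buffer blank for [buffer_threshold()]; ignored
#'   if `threshold` is given.
#' @param threshold Explicit intensity threshold.
#' @param offset_sd Passed to [buffer_threshold()].
#' @inheritParams segment_droplets
#' @inheritParams filter_droplets
#' @return As [droplet_coverage()].
#' @export
quantify_droplets <- function(image, buffer_image = NULL, threshold = NULL,
                              offset_sd = 0, connectivity = 8,
                              max_eccentricity = 0.9,
                              min_diameter_um = 1) {
  if (is.null(threshold)) {
    if (is.null(buffer_image)) {
      rlang::abort("Provide either `threshold` or `buffer_image`.")
    }
    threshold <- buffer_threshold(buffer_image, offset_sd)
  }
  regions <- segment_droplets(image, threshold, connectivity)
  droplet_coverage(
    filter_droplets(regions, max_eccentricity, min_diameter_um), image
  )
}

#' Aggregate coverage over replicates of a condition
#'
#' @param coverage Row-bound [droplet_coverage()] results.
#' @return Per-condition mean, sd and n of percent coverage.
#' @export
aggregate_coverage <- function(coverage) {
  stopifnot(is.data.frame(coverage),
            all(c("percent_coverage", "condition") %in% names(coverage)))
  coverage %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(
      mean_coverage = mean(.data$percent_coverage),
      sd_coverage = stats::sd(.data$percent_coverage),
      n = dplyr::n(),
      .groups = "drop"
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
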