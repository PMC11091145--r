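# Data model, I/O and preprocessing for pixel-by-feature MSI matrices.

#' Construct a spectral image
#'
#' A `spectral_image` is the unit on which all MSI stages operate: a set of
#' pixels on a regular grid, each carrying an intensity vector over m/z
#' features. Coordinates are 0-based `(row, col)` integers; the physical
#' pixel edge length defaults to the 5 um of high-resolution MALDI-TOF
#' acquisitions.
#'
#' @param coords integer matrix or data.frame with columns `x`, `y`
#'   (0-based pixel column/row indices), one row per pixel, no duplicates.
#' @param mz numeric vector of m/z values, strictly increasing.
#' @param intensities numeric matrix, `nrow(coords)` x `length(mz)`,
#'   non-negative.
#' @param pixel_size_um pixel edge length in micrometres (default 5).
#' @param normalized logical; `TRUE` once every pixel row sums to 1 (see
#'   [tic_normalize()]).
#' @return an object of class `spectral_image` with fields `coords`, `mz`,
#'   `intensities`, `pixel_size_um`, `normalized`.
#' @examples
#' img <- spectral_image(cbind(x = c(0, 1), y = c(0, 0)),
#'                       mz = c(400.1, 500.2),
#'                       intensities = rbind(c(1, 2), c(3, 4)))
#' img
#' @export
spectral_image <- function(coords, mz, intensities, pixel_size_um = 5,
                           normalized = FALSE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop_arg("coords must have two columns (x, y)")
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  mz <- as.numeric(mz)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(coords)) {
    stop_arg("intensities has %d rows but coords has %d pixels",
             nrow(intensities), nrow(coords))
  }
  if (ncol(intensities) != length(mz)) {
    stop_arg("intensities has %d columns but mz has %d entries",
             ncol(intensities), length(mz))
  }
  if (any(duplicated(coords))) {
    i <- which(duplicated(coords))[1L]
    stop_arg("duplicate pixel coordinate (%d, %d)", coords[i, 1], coords[i, 2])
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop_arg("mz values must be strictly increasing")
  }
  if (any(mz <= 0)) stop_arg("mz values must be positive")
  if (any(intensities < 0)) stop_arg("intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop_arg("pixel_size_um must be a positive number")
  }
  colnames(intensities) <- format(mz, trim = TRUE, digits = 15)
  structure(
    list(coords = coords, mz = mz, intensities = intensities,
         pixel_size_um = as.numeric(pixel_size_um),
         normalized = isTRUE(normalized)),
    class = "spectral_image"
  )
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf("spectral_image: %d pixels x %d features (m/z %.4g-%.4g), %g um pixels%s\n",
              nrow(x$intensities), length(x$mz),
              min(x$mz), max(x$mz), x$pixel_size_um,
              if (x$normalized) ", TIC-normalized" else ""))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) dim(x$intensities)

#' Read / write the pixel-matrix CSV dialect
#'
#' The reference exchange format mirrors a per-pixel feature export: a header
#' row `x,y,<mz1>,<mz2>,...` followed by one row per pixel with integer
#' coordinates and non-negative intensities. m/z columns may appear in any
#' order in the file; they are sorted on read and the intensity columns are
#' permuted accordingly.
#'
#' @param path file path.
#' @param pixel_size_um pixel edge length to attach to the image (the CSV
#'   itself carries no physical metadata).
#' @return [read_pixel_csv()] returns a [spectral_image()];
#'   [write_pixel_csv()] returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' img <- spectral_image(cbind(x = 0:1, y = c(0L, 0L)), c(400.5, 502.3),
#'                       rbind(c(1, 2), c(0.5, 4)))
#' write_pixel_csv(img, f)
#' read_pixel_csv(f)
#' @export
read_pixel_csv <- function(path, pixel_size_um = 5) {
  if (!file.exists(path)) stop_arg("pixel CSV not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L) stop_arg("pixel CSV needs x, y and at least one m/z column")
  nms <- names(df)
  if (!identical(tolower(nms[1:2]), c("x", "y"))) {
    stop_arg("pixel CSV header must start with x, y")
  }
  mz <- suppressWarnings(as.numeric(nms[-(1:2)]))
  if (any(is.na(mz))) stop_arg("non-numeric m/z column header in %s", path)
  inten <- as.matrix(df[, -(1:2), drop = FALSE])
  if (any(is.na(inten))) stop_arg("ragged or non-numeric intensity rows in %s", path)
  if (any(inten < 0)) stop_arg("negative intensity in %s", path)
  ord <- order(mz)
  spectral_image(coords = as.matrix(df[, 1:2]), mz = mz[ord],
                 intensities = inten[, ord, drop = FALSE],
                 pixel_size_um = pixel_size_um)
}

#' @rdname read_pixel_csv
#' @param image a [spectral_image()].
#' @export
write_pixel_csv <- function(image, path) {
  stopifnot(inherits(image, "spectral_image"))
  df <- data.frame(x = image$coords[, "x"], y = image$coords[, "y"],
                   image$intensities, check.names = FALSE)
  names(df) <- c("x", "y", format(image$mz, trim = TRUE, digits = 15))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total-ion-count normalization
#'
#' Divides each pixel's intensity vector by its sum (the total ion count) so
#' pixels are comparable regardless of ionization efficiency. Pixels whose
#' TIC is zero carry no information and are dropped; the number dropped is
#' recorded in the `dropped_pixels` attribute.
#'
#' @param image an unnormalized [spectral_image()].
#' @return a normalized `spectral_image`; attribute `dropped_pixels` gives
#'   the count of removed zero-TIC pixels.
#' @examples
#' img <- spectral_image(cbind(x = 0:1, y = c(0L, 0L)), c(400, 500),
#'                       rbind(c(2, 3), c(0, 0)))
#' norm <- tic_normalize(img)
#' attr(norm, "dropped_pixels")  # 1
#' @export
tic_normalize <- function(image) {
  stopifnot(inherits(image, "spectral_image"))
  if (image$normalized) stop_arg("image is already TIC-normalized")
  tic <- rowSums(image$intensities)
  keep <- tic > 0
  if (!any(keep)) stop_arg("all pixels have zero total ion count")
  out <- spectral_image(
    coords = image$coords[keep, , drop = FALSE],
    mz = image$mz,
    intensities = image$intensities[keep, , drop = FALSE] / tic[keep],
    pixel_size_um = image$pixel_size_um,
    normalized = TRUE
  )
  attr(out, "dropped_pixels") <- sum(!keep)
  out
}

#' Integer count matrix from a normalized image
#'
#' Converts TIC-normalized fractions to pseudo-counts by multiplying by 100
#' and taking the integer part (floor), the representation expected by
#' count-based variance-stabilizing transforms.
#'
#' @param image a normalized [spectral_image()].
#' @return integer matrix, pixels x features, entries in 0..100.
#' @export
to_count_matrix <- function(image) {
  stopifnot(inherits(image, "spectral_image"))
  if (!image$normalized) stop_arg("to_count_matrix requires a TIC-normalized image")
  m <- floor(image$intensities * 100)
  storage.mode(m) <- "integer"
  m
}

#' Feature reference table
#'
#' Builds the per-feature metadata table used for feature selection and
#' isotopologue bookkeeping. `kind` distinguishes lipids (used for
#' segmentation), metabolite/isotopologue channels (used for enrichment) and
#' MALDI matrix-derived signals (always excluded from lipid selection).
#'
#' @param mz numeric, feature m/z.
#' @param name optional feature name.
#' @param n_carbons optional carbon count (metabolite/isotopologue rows).
#' @param kind one of `"lipid"`, `"metabolite"`, `"isotopologue"`, `"matrix"`.
#' @param snr optional signal-to-noise ratio, taken as given (the upstream
#'   peak picker's estimate).
#' @param isotopologue_index optional k of M+k; must be <= `n_carbons`.
#' @return a `data.frame` of class `feature_table`.
#' @export
feature_table <- function(mz, name = NA_character_, n_carbons = NA_integer_,
                          kind = "lipid", snr = NA_real_,
                          isotopologue_index = NA_integer_) {
  df <- data.frame(mz = as.numeric(mz), name = as.character(name),
                   n_carbons = as.integer(n_carbons),
                   kind = as.character(kind), snr = as.numeric(snr),
                   isotopologue_index = as.integer(isotopologue_index),
                   stringsAsFactors = FALSE)
  bad <- !df$kind %in% c("lipid", "metabolite", "isotopologue", "matrix")
  if (any(bad)) stop_arg("unknown feature kind: %s", df$kind[which(bad)[1L]])
  iso <- df$kind == "isotopologue"
  if (any(iso & (is.na(df$n_carbons) | is.na(df$isotopologue_index)))) {
    stop_arg("isotopologue features need n_carbons and isotopologue_index")
  }
  if (any(iso & df$isotopologue_index > df$n_carbons, na.rm = TRUE)) {
    stop_arg("isotopologue_index exceeds n_carbons")
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @rdname feature_table
#' @param path TSV path with columns mz, name, n_carbons, kind, snr,
#'   isotopologue_index.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  feature_table(df$mz, df$name, df$n_carbons, df$kind, df$snr,
                df$isotopologue_index)
}

#' @rdname feature_table
#' @param table a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select lipid features for segmentation
#'
#' Keeps features suitable for lipid-profile clustering: m/z at or above
#' `min_mz` (glycerophospholipid range), signal-to-noise at or above
#' `min_snr`, and not flagged as MALDI matrix signals. Feature order is
#' preserved.
#'
#' @param image a [spectral_image()].
#' @param table a [feature_table()] covering every image feature, in image
#'   feature order.
#' @param min_mz minimum m/z (default 400).
#' @param min_snr minimum signal-to-noise ratio (default 3).
#' @return a `spectral_image` restricted to qualifying features; attribute
#'   `kept` holds the logical selection mask.
#' @export
select_lipid_features <- function(image, table, min_mz = 400, min_snr = 3) {
  stopifnot(inherits(image, "spectral_image"))
  if (nrow(table) != length(image$mz)) {
    stop_arg("feature table has %d rows but image has %d features",
             nrow(table), length(image$mz))
  }
  snr <- ifelse(is.na(table$snr), Inf, table$snr)
  keep <- image$mz >= min_mz & snr >= min_snr & table$kind != "matrix"
  if (!any(keep)) stop_arg("no feature passes the lipid selection filters")
  out <- spectral_image(image$coords, image$mz[keep],
                        image$intensities[, keep, drop = FALSE],
                        pixel_size_um = image$pixel_size_um,
                        normalized = image$normalized)
  attr(out, "kept") <- keep
  out
}

#' Annotate observed m/z against a reference table
#'
#' Matches each observed m/z to the reference entry with the smallest ppm
#' error, provided that error is within `tol_ppm`. An exact tie between two
#' reference candidates is ambiguous and left unmatched with a flag.
#'
#' @param observed_mz numeric vector of observed m/z values.
#' @param reference a [feature_table()] (or data.frame with `mz`, `name`).
#' @param tol_ppm matching tolerance in parts per million (default 20).
#' @return data.frame with one row per observed m/z: `observed_mz`,
#'   `ref_index` (NA if unmatched), `ref_mz`, `name`, `ppm_error`,
#'   `ambiguous`.
#' @examples
#' ref <- feature_table(mz = c(885.5499, 885.5723), name = c("PI 38:4", "PS 40:4"))
#' annotate_features(885.549, ref)
#' @export
annotate_features <- function(observed_mz, reference, tol_ppm = 20) {
  if (any(reference$mz <= 0)) stop_arg("reference m/z must be positive")
  res <- lapply(observed_mz, function(obs) {
    ppm <- abs(obs - reference$mz) / reference$mz * 1e6
    ok <- which(ppm <= tol_ppm)
    if (length(ok) == 0L) {
      return(data.frame(observed_mz = obs, ref_index = NA_integer_,
                        ref_mz = NA_real_, name = NA_character_,
                        ppm_error = NA_real_, ambiguous = FALSE))
    }
    best <- min(ppm[ok])
    hits <- ok[ppm[ok] == best]
    if (length(hits) > 1L) {
      return(data.frame(observed_mz = obs, ref_index = NA_integer_,
                        ref_mz = NA_real_, name = NA_character_,
                        ppm_error = best, ambiguous = TRUE))
    }
    data.frame(observed_mz = obs, ref_index = hits,
               ref_mz = reference$mz[hits],
               name = as.character(reference$name[hits]),
               ppm_error = best, ambiguous = FALSE)
  })
  do.call(rbind, res)
}

#' Hotspot removal by quantile clipping
#'
#' Caps values above the empirical `quantile` (linear interpolation between
#' order statistics, R type 7) at that quantile, the standard treatment for
#' isolated hot pixels before rendering pseudo-images.
#'
#' @param values numeric vector (NAs pass through untouched).
#' @param quantile clipping quantile in (0, 1), default 0.99.
#' @return clipped numeric vector.
#' @export
hotspot_clip <- function(values, quantile = 0.99) {
  if (length(values) == 0L) stop_arg("hotspot_clip needs a non-empty vector")
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1) {
    stop_arg("quantile must lie strictly between 0 and 1")
  }
  q <- stats::quantile(values, probs = quantile, na.rm = TRUE,
                       names = FALSE, type = 7)
  pmin(values, q)
}

#' Dataset-level pixel bookkeeping
#'
#' Totals over a set of sections: pixel counts, mean pixels per section, and
#' measured areas from the pixel size. Accepts either a list of
#' [spectral_image()] objects or explicit totals.
#'
#' @param images list of `spectral_image` objects sharing one pixel size, or
#'   `NULL` when `total_pixels`/`n_sections` are given directly.
#' @param total_pixels,n_sections explicit totals (used when `images` is NULL).
#' @param pixel_size_um pixel edge length in micrometres.
#' @return list with `n_sections`, `total_pixels`, `mean_pixels_per_section`
#'   (rounded), `area_mm2_per_section`, `mean_area_mm2` (1 decimal).
#' @examples
#' dataset_stats(total_pixels = 2394033, n_sections = 33)
#' @export
dataset_stats <- function(images = NULL, total_pixels = NULL,
                          n_sections = NULL, pixel_size_um = 5) {
  if (!is.null(images)) {
    if (length(images) == 0L) stop_arg("empty image list")
    sizes <- vapply(images, function(im) im$pixel_size_um, numeric(1))
    if (length(unique(sizes)) != 1L) stop_arg("images must share one pixel size")
    pixel_size_um <- sizes[1L]
    per_section <- vapply(images, function(im) nrow(im$intensities), numeric(1))
    total_pixels <- sum(per_section)
    n_sections <- length(images)
  } else {
    if (is.null(total_pixels) || is.null(n_sections) || n_sections < 1) {
      stop_arg("supply images or total_pixels and n_sections")
    }
    per_section <- rep(total_pixels / n_sections, n_sections)
  }
  px_area_mm2 <- (pixel_size_um / 1000)^2
  list(
    n_sections = as.integer(n_sections),
    total_pixels = total_pixels,
    mean_pixels_per_section = round_half_up(total_pixels / n_sections),
    area_mm2_per_section = per_section * px_area_mm2,
    mean_area_mm2 = round_half_up(mean(per_section) * px_area_mm2, 1)
  )
}
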