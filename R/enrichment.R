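# Per-pixel corrected fraction enrichments, cluster summaries, fold changes
# and hotspot-clipped pseudo-images.

#' Per-pixel corrected fraction enrichments
#'
#' For every metabolite with isotopologue channels in the image, corrects
#' each pixel's observed M+0..M+n intensity vector for natural abundance and
#' tracer purity, then converts to fraction enrichments. Pixels with an
#' all-zero channel set are masked (NA), not errors. Pixels whose
#' unconstrained solution is already non-negative take a vectorized direct
#' solve; the rest fall back to non-negative least squares.
#'
#' @param image a [spectral_image()] containing isotopologue features (raw
#'   or TIC-normalized; fractions are scale invariant per pixel).
#' @param features the matching [feature_table()] (image feature order).
#' @param p13c natural 13C abundance (default 0.0107).
#' @param tracer_purity tracer purity (default 0.99).
#' @param method `"nnls"` (default) or `"solve"`.
#' @return named list, one entry per metabolite: matrix pixels x (n+1) of
#'   corrected fractions (rows of NA where masked). Attribute `n_masked`
#'   counts masked pixels per metabolite.
#' @export
pixel_enrichments <- function(image, features, p13c = 0.0107,
                              tracer_purity = 0.99,
                              method = c("nnls", "solve")) {
  method <- match.arg(method)
  stopifnot(inherits(image, "spectral_image"))
  if (nrow(features) != length(image$mz)) {
    stop_arg("feature table does not match image features")
  }
  iso <- features$kind == "isotopologue"
  if (!any(iso)) stop_arg("image carries no isotopologue features")
  mets <- unique(sub("_M\\d+$", "", features$name[iso]))
  out <- list()
  n_masked <- integer(0)
  for (m in mets) {
    rows <- which(iso & sub("_M\\d+$", "", features$name) == m)
    n <- features$n_carbons[rows[1L]]
    ord <- order(features$isotopologue_index[rows])
    cols <- rows[ord]
    if (length(cols) != n + 1L) {
      stop_arg("metabolite %s: expected %d isotopologue channels, found %d",
               m, n + 1L, length(cols))
    }
    obs <- image$intensities[, cols, drop = FALSE]
    model <- build_forward_matrix(n, p13c = p13c, tracer_purity = tracer_purity)
    tot <- rowSums(obs)
    fr <- matrix(NA_real_, nrow(obs), n + 1L)
    ok <- tot > 0
    if (any(ok)) {
      b <- obs[ok, , drop = FALSE] / tot[ok]
      x <- t(solve(model$forward, t(b)))      # vectorized direct inverse
      if (method == "nnls") {
        wn <- which(rowSums(x < -1e-12) > 0)
        for (i in wn) x[i, ] <- nnls_solve(model$forward, b[i, ])
        x[x < 0] <- 0
      }
      s <- rowSums(x)
      good <- s > 0
      x[good, ] <- x[good, , drop = FALSE] / s[good]
      x[!good, ] <- NA_real_
      fr[ok, ] <- x
    }
    colnames(fr) <- paste0("M", 0:n)
    out[[m]] <- fr
    n_masked[m] <- sum(!ok)
  }
  attr(out, "n_masked") <- n_masked
  out
}

#' Summarize per-pixel enrichments by cluster
#'
#' Arithmetic mean and standard deviation of each corrected isotopologue
#' fraction over the unmasked pixels of every cluster. Clusters whose pixels
#' are all masked for a channel are reported masked (NA) with `n = 0`.
#'
#' @param per_pixel result of [pixel_enrichments()].
#' @param map a [cluster_pixels()] result covering the same pixels, or an
#'   integer cluster vector.
#' @return data.frame: `cluster`, `metabolite`, `k` (isotopologue index),
#'   `mean`, `sd`, `n` (unmasked pixels).
#' @export
summarize_by_cluster <- function(per_pixel, map) {
  cl <- if (inherits(map, "cluster_map")) map$pixel_cluster else as.integer(map)
  n_px <- nrow(per_pixel[[1L]])
  if (length(cl) != n_px) stop_arg("cluster map covers %d pixels, enrichments %d",
                                   length(cl), n_px)
  rows <- list()
  for (m in names(per_pixel)) {
    fr <- per_pixel[[m]]
    for (k in 0:(ncol(fr) - 1L)) {
      v <- fr[, k + 1L]
      for (c_id in sort(unique(cl))) {
        vi <- v[cl == c_id]
        vi_ok <- vi[!is.na(vi)]
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = c_id, metabolite = m, k = k,
          mean = if (length(vi_ok)) mean(vi_ok) else NA_real_,
          sd = if (length(vi_ok) > 1L) stats::sd(vi_ok) else
               if (length(vi_ok) == 1L) 0 else NA_real_,
          n = length(vi_ok))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log2 fold change of cluster means vs a baseline cluster
#'
#' @param per_cluster data.frame from [summarize_by_cluster()].
#' @param baseline cluster id used as the reference.
#' @param eps guard added to both means (default 1e-9); means of exactly 0
#'   are reported with `floored = TRUE`.
#' @return `per_cluster` with columns `log2fc` and `floored` added.
#' @export
log2fc_vs_baseline <- function(per_cluster, baseline, eps = 1e-9) {
  base <- per_cluster[per_cluster$cluster == baseline, ]
  if (nrow(base) == 0L) stop_arg("baseline cluster %s not present", baseline)
  if (anyNA(base$mean)) stop_arg("baseline cluster %s has masked means", baseline)
  key <- function(df) paste(df$metabolite, df$k)
  bmean <- stats::setNames(base$mean, key(base))
  b <- bmean[key(per_cluster)]
  per_cluster$log2fc <- log2((per_cluster$mean + eps) / (b + eps))
  per_cluster$floored <- !is.na(per_cluster$mean) & per_cluster$mean == 0
  per_cluster
}

#' Render one channel as a hotspot-clipped pseudo-image
#'
#' Places per-pixel values onto their grid coordinates after clipping at the
#' upper `quantile` ([hotspot_clip()]). Grid cells without a pixel, and
#' masked values, stay NA — masked is not zero.
#'
#' @param values numeric per-pixel vector (NA = masked).
#' @param coords integer matrix with columns `x`, `y` (0-based).
#' @param quantile hotspot-removal quantile (default 0.99).
#' @return numeric matrix (rows = y, cols = x) with NA for missing/masked
#'   cells.
#' @export
pseudo_image <- function(values, coords, quantile = 0.99) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(values)) stop_arg("coords/value length mismatch")
  if (any(coords < 0)) stop_arg("coords must be non-negative (0-based)")
  clipped <- if (all(is.na(values))) values else hotspot_clip(values, quantile)
  h <- max(coords[, 2]) + 1L
  w <- max(coords[, 1]) + 1L
  grid <- matrix(NA_real_, nrow = h, ncol = w)
  grid[cbind(coords[, 2] + 1L, coords[, 1] + 1L)] <- clipped
  grid
}
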