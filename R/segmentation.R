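# Pixel segmentation by lipid profile, cluster annotation, differential
# features and metabolite-channel transfer between datasets.

# Variance-stabilized, per-feature scaled representation of the count
# matrix: log1p then center/scale each feature to unit variance
# (zero-variance features stay centered at 0).
vst_scale <- function(counts, center = NULL, scale = NULL) {
  x <- log1p(counts)
  if (is.null(center)) center <- colMeans(x)
  x <- sweep(x, 2L, center, "-")
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  }
  x <- sweep(x, 2L, scale, "/")
  attr(x, "vst_center") <- center
  attr(x, "vst_scale") <- scale
  x
}

#' Cluster pixels into phenotypes by lipid profile
#'
#' Variance-stabilizes the integer count matrix (log1p, per-feature unit
#' variance), reduces it to `n_components` principal components, and
#' partitions pixels with k-means under a fixed seed. Deterministic for a
#' fixed seed and invariant (up to label permutation) to pixel order.
#'
#' @param image a TIC-normalized [spectral_image()] restricted to lipid
#'   features (see [select_lipid_features()]).
#' @param n_clusters number of clusters (>= 2).
#' @param seed integer RNG seed for the k-means initialization.
#' @param n_components number of principal components retained (default 20,
#'   capped at the data rank).
#' @return object of class `cluster_map`: `pixel_cluster` (integer per
#'   pixel), `coords`, `annotation` (empty until [annotate_clusters()]),
#'   `centers` (k-means centers in PC space).
#' @export
cluster_pixels <- function(image, n_clusters, seed = 1L, n_components = 20) {
  stopifnot(inherits(image, "spectral_image"))
  if (n_clusters < 2) stop_arg("n_clusters must be >= 2")
  n_px <- nrow(image$intensities)
  if (n_px < n_clusters) {
    stop_arg("%d pixels cannot form %d clusters", n_px, n_clusters)
  }
  counts <- to_count_matrix(image)
  x <- vst_scale(counts)
  ncomp <- min(n_components, ncol(x), n_px - 1L)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = ncomp)
  emb <- pc$x
  km <- with_seed(seed, stats::kmeans(emb, centers = n_clusters,
                                      nstart = 10, iter.max = 100))
  # canonical label order: clusters renumbered by first pixel occurrence so
  # assignments are invariant to k-means' internal label arbitrariness
  first <- match(seq_len(n_clusters), km$cluster)
  ord <- order(first)
  relabel <- integer(n_clusters); relabel[ord] <- seq_len(n_clusters)
  structure(
    list(pixel_cluster = relabel[km$cluster],
         coords = image$coords,
         annotation = character(0),
         centers = km$centers[ord, , drop = FALSE]),
    class = "cluster_map"
  )
}

#' @export
print.cluster_map <- function(x, ...) {
  tab <- table(x$pixel_cluster)
  cat(sprintf("cluster_map: %d pixels in %d clusters\n",
              length(x$pixel_cluster), length(tab)))
  for (k in names(tab)) {
    lbl <- if (length(x$annotation) >= as.integer(k) &&
               !is.na(x$annotation[as.integer(k)])) {
      paste0(" (", x$annotation[as.integer(k)], ")")
    } else ""
    cat(sprintf("  cluster %s%s: %d pixels (%.1f%%)\n", k, lbl, tab[[k]],
                100 * tab[[k]] / length(x$pixel_cluster)))
  }
  invisible(x)
}

#' Annotate clusters from marker features
#'
#' Labels each cluster with the phenotype whose marker features have the
#' highest mean intensity within the cluster — an in-silico surrogate for
#' matching segmentation clusters to immunostained cell types. The margin
#' between the best and second-best phenotype is reported; a tie at machine
#' precision (including all-zero markers) leaves the cluster unlabeled with
#' a flag.
#'
#' @param map a [cluster_pixels()] result.
#' @param image the [spectral_image()] the map was derived from (same pixel
#'   order).
#' @param markers named list: phenotype -> character vector of feature
#'   names; names are matched against `colnames(image$intensities)` or
#'   against formatted m/z values.
#' @param feature_names optional explicit feature-name vector aligned with
#'   image columns.
#' @return the map with `annotation` (per-cluster phenotype label, NA where
#'   tied), `annotation_margin`, `annotation_flag`.
#' @export
annotate_clusters <- function(map, image, markers, feature_names = NULL) {
  stopifnot(inherits(map, "cluster_map"), inherits(image, "spectral_image"))
  fn <- feature_names %||% colnames(image$intensities)
  n_clusters <- max(map$pixel_cluster)
  pheno <- names(markers)
  score <- matrix(NA_real_, n_clusters, length(pheno),
                  dimnames = list(NULL, pheno))
  for (p in pheno) {
    idx <- match(markers[[p]], fn)
    if (anyNA(idx)) {
      stop_arg("marker feature(s) not in image: %s",
               paste(markers[[p]][is.na(idx)], collapse = ", "))
    }
    mi <- rowMeans(image$intensities[, idx, drop = FALSE])
    score[, p] <- vapply(seq_len(n_clusters), function(k) {
      mean(mi[map$pixel_cluster == k])
    }, numeric(1))
  }
  ann <- rep(NA_character_, n_clusters)
  margin <- rep(NA_real_, n_clusters)
  flag <- rep(FALSE, n_clusters)
  for (k in seq_len(n_clusters)) {
    s <- sort(score[k, ], decreasing = TRUE)
    if (length(s) > 1L && abs(s[1] - s[2]) <= .Machine$double.eps * max(1, abs(s[1]))) {
      flag[k] <- TRUE
    } else {
      ann[k] <- names(s)[1L]
      margin[k] <- if (length(s) > 1L) s[1] - s[2] else Inf
    }
  }
  map$annotation <- ann
  map$annotation_margin <- margin
  map$annotation_flag <- flag
  map
}

#' Differential features of one cluster vs all other pixels
#'
#' For every feature, the log2 fold change of the in-cluster mean over the
#' out-of-cluster mean (pseudo-count guarded) and a two-sided Wilcoxon
#' rank-sum p-value, with Benjamini-Hochberg adjustment across features.
#'
#' @param image a [spectral_image()].
#' @param map a matching [cluster_pixels()] result.
#' @param cluster_id the cluster to contrast.
#' @param eps pseudo-count added to both means (default 1e-9).
#' @return data.frame: `feature`, `mz`, `mean_in`, `mean_out`, `log2fc`,
#'   `p_value`, `p_adj`, ordered by decreasing `log2fc`.
#' @export
differential_features <- function(image, map, cluster_id, eps = 1e-9) {
  stopifnot(inherits(image, "spectral_image"), inherits(map, "cluster_map"))
  inside <- map$pixel_cluster == cluster_id
  if (sum(inside) < 2L || sum(!inside) < 2L) {
    stop_arg("cluster %s needs >= 2 pixels inside and outside", cluster_id)
  }
  xi <- image$intensities[inside, , drop = FALSE]
  xo <- image$intensities[!inside, , drop = FALSE]
  mean_in <- colMeans(xi)
  mean_out <- colMeans(xo)
  l2fc <- log2((mean_in + eps) / (mean_out + eps))
  p <- vapply(seq_along(image$mz), function(j) {
    stats::wilcox.test(xi[, j], xo[, j], exact = FALSE)$p.value
  }, numeric(1))
  res <- data.frame(
    feature = colnames(image$intensities) %||% as.character(image$mz),
    mz = image$mz, mean_in = mean_in, mean_out = mean_out,
    log2fc = l2fc, p_value = p, p_adj = stats::p.adjust(p, "BH"),
    row.names = NULL
  )
  res[order(-res$log2fc), ]
}

#' Transfer metabolite channels from a reference onto a query dataset
#'
#' Imputes metabolite channels for query pixels that carry only lipid
#' features: each query pixel receives the inverse-distance-weighted mean of
#' the metabolite values of its `k` nearest reference pixels in the shared,
#' variance-stabilized lipid space (scaled by the reference's statistics so
#' both datasets live in one coordinate system). Imputed values are convex
#' combinations of reference values, so they never extrapolate outside the
#' reference range per channel.
#'
#' @param reference_lipids reference pixels x shared-lipid matrix (raw or
#'   normalized intensities).
#' @param reference_metabolites reference pixels x metabolite-channel matrix.
#' @param query_lipids query pixels x shared-lipid matrix (same feature
#'   order as `reference_lipids`).
#' @param k number of nearest neighbours (default 10).
#' @param eps distance guard in the inverse-distance weights (default 1e-9).
#' @return matrix query pixels x metabolite channels.
#' @export
transfer_labels <- function(reference_lipids, reference_metabolites,
                            query_lipids, k = 10, eps = 1e-9) {
  reference_lipids <- as.matrix(reference_lipids)
  query_lipids <- as.matrix(query_lipids)
  reference_metabolites <- as.matrix(reference_metabolites)
  if (ncol(reference_lipids) == 0L || ncol(query_lipids) == 0L) {
    stop_arg("shared lipid feature set is empty")
  }
  if (ncol(reference_lipids) != ncol(query_lipids)) {
    stop_arg("reference and query must share the lipid feature set")
  }
  if (nrow(reference_metabolites) != nrow(reference_lipids)) {
    stop_arg("reference metabolite rows must match reference lipid rows")
  }
  k <- min(k, nrow(reference_lipids))
  ref <- vst_scale(reference_lipids)
  qry <- vst_scale(query_lipids, center = attr(ref, "vst_center"),
                   scale = attr(ref, "vst_scale"))
  ref_sq <- rowSums(ref^2)
  out <- matrix(NA_real_, nrow(qry), ncol(reference_metabolites))
  colnames(out) <- colnames(reference_metabolites)
  block <- 512L
  for (start in seq(1L, nrow(qry), by = block)) {
    idx <- start:min(start + block - 1L, nrow(qry))
    qb <- qry[idx, , drop = FALSE]
    d2 <- outer(rowSums(qb^2), ref_sq, "+") - 2 * tcrossprod(qb, ref)
    d2[d2 < 0] <- 0
    for (i in seq_along(idx)) {
      nn <- order(d2[i, ])[seq_len(k)]
      w <- 1 / (sqrt(d2[i, nn]) + eps)
      w <- w / sum(w)
      out[idx[i], ] <- as.numeric(w %*% reference_metabolites[nn, , drop = FALSE])
    }
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Standard chance-corrected agreement between two partitions of the same
#' pixels; 1 means identical partitions (up to relabeling), 0 is the
#' expectation under independent random labelings.
#'
#' @param a,b integer/character label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_arg("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
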