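# Pixel clustering, marker annotation, differential features, transfer.

prepare_lipids <- function(d) {
  norm <- tic_normalize(d$image)
  list(norm = norm,
       lipids = select_lipid_features(norm, d$features),
       names = d$features$name[d$features$kind == "lipid" &
                                 d$features$mz >= 400])
}

test_that("noiseless phenotypes are recovered exactly and deterministically", {
  d <- noiseless_dataset(n_types = 3, seed = 21)
  pl <- prepare_lipids(d)
  map <- cluster_pixels(pl$lipids, n_clusters = 3, seed = 1)
  expect_equal(adjusted_rand_index(map$pixel_cluster, d$truth$pixel_labels), 1)
  map2 <- cluster_pixels(pl$lipids, n_clusters = 3, seed = 1)
  expect_identical(map$pixel_cluster, map2$pixel_cluster)
  # partition: every pixel exactly one id
  expect_equal(length(map$pixel_cluster), nrow(pl$lipids$intensities))
  expect_true(all(map$pixel_cluster %in% 1:3))
  expect_error(cluster_pixels(pl$lipids, n_clusters = 1), "n_clusters")
})

test_that("noisy 4-phenotype segmentation still reaches ARI >= 0.9", {
  d <- simulate_msi_dataset(32, 32, 4, noise_sd = 0.05, seed = 13)
  pl <- prepare_lipids(d)
  map <- cluster_pixels(pl$lipids, n_clusters = 4, seed = 2)
  expect_gte(adjusted_rand_index(map$pixel_cluster, d$truth$pixel_labels), 0.9)
})

test_that("pixel order does not change the partition (up to relabeling)", {
  d <- noiseless_dataset(n_types = 3, seed = 23)
  pl <- prepare_lipids(d)
  map <- cluster_pixels(pl$lipids, 3, seed = 5)
  set.seed(1); perm <- sample(nrow(pl$lipids$intensities))
  shuffled <- spectral_image(pl$lipids$coords[perm, ], pl$lipids$mz,
                             pl$lipids$intensities[perm, ],
                             normalized = TRUE)
  map_p <- cluster_pixels(shuffled, 3, seed = 5)
  expect_equal(adjusted_rand_index(map_p$pixel_cluster,
                                   map$pixel_cluster[perm]), 1)
})

test_that("marker annotation labels clusters by dominant marker set", {
  d <- noiseless_dataset(n_types = 2, seed = 25)
  pl <- prepare_lipids(d)
  map <- cluster_pixels(pl$lipids, 2, seed = 1)
  markers <- list(type1 = "lipid_1", type2 = "lipid_2")
  ann <- annotate_clusters(map, pl$lipids, markers, feature_names = pl$names)
  truth_of_cluster <- vapply(1:2, function(k) {
    as.integer(names(which.max(table(
      d$truth$pixel_labels[map$pixel_cluster == k]))))
  }, integer(1))
  expect_equal(ann$annotation, paste0("type", truth_of_cluster))
  expect_true(all(ann$annotation_margin > 0))
  # swapped markers -> swapped labels
  ann_sw <- annotate_clusters(map, pl$lipids,
                              list(type1 = "lipid_2", type2 = "lipid_1"),
                              feature_names = pl$names)
  expect_equal(ann_sw$annotation, paste0("type", 3 - truth_of_cluster))
  # all-zero marker intensities -> unlabeled + flag
  zero_img <- spectral_image(pl$lipids$coords, c(400.5, 500.5),
                             matrix(0, nrow(pl$lipids$intensities), 2))
  ann0 <- annotate_clusters(map, zero_img, list(a = "f1", b = "f2"),
                            feature_names = c("f1", "f2"))
  expect_true(all(is.na(ann0$annotation)))
  expect_true(all(ann0$annotation_flag))
})

test_that("differential features report fold change and rank-sum p", {
  set.seed(31)
  n <- 60
  cl <- rep(1:2, each = n)
  # feature 1: 10x higher in cluster 1; feature 2: identical distributions;
  # feature 3: zero outside cluster 1
  f1 <- c(rnorm(n, 100, 1), rnorm(n, 10, 0.1))
  f2 <- rnorm(2 * n, 50, 5)
  f3 <- c(abs(rnorm(n, 5, 0.5)), rep(0, n))
  img <- spectral_image(cbind(x = 0:(2 * n - 1), y = rep(0L, 2 * n)),
                        c(400.1, 500.1, 600.1), cbind(f1, f2, f3))
  map <- structure(list(pixel_cluster = cl, coords = img$coords,
                        annotation = character(0)), class = "cluster_map")
  res <- differential_features(img, map, 1)
  r1 <- res[res$mz == 400.1, ]
  expect_equal(r1$log2fc, log2(10), tolerance = 0.01)
  expect_lt(r1$p_adj, 1e-10)
  r2 <- res[res$mz == 500.1, ]
  expect_lt(abs(r2$log2fc), 0.1)
  expect_gt(r2$p_value, 0.05)
  r3 <- res[res$mz == 600.1, ]
  expect_true(is.finite(r3$log2fc))  # pseudo-count guards the zero mean
  singleton <- structure(list(pixel_cluster = c(1L, rep(2L, 2 * n - 1)),
                              coords = img$coords,
                              annotation = character(0)),
                         class = "cluster_map")
  expect_error(differential_features(img, singleton, 1), ">= 2 pixels")
})

test_that("label transfer is exact on identity and bounded by the reference", {
  set.seed(41)
  ref_lip <- matrix(runif(200, 0, 50), nrow = 40)
  ref_met <- cbind(a = runif(40), b = runif(40, 10, 20))
  imputed <- transfer_labels(ref_lip, ref_met, ref_lip, k = 5)
  expect_lt(max(abs(imputed - ref_met)), 1e-6)
  # constant reference channel -> constant imputation
  const <- transfer_labels(ref_lip, cbind(c = rep(3.5, 40)),
                           matrix(runif(50, 0, 50), nrow = 10), k = 7)
  expect_equal(unname(const[, 1]), rep(3.5, 10))
  # never extrapolates outside the reference range per channel
  qry <- matrix(runif(150, 0, 80), nrow = 30)
  imp <- transfer_labels(ref_lip, ref_met, qry, k = 10)
  for (j in 1:2) {
    expect_gte(min(imp[, j]), min(ref_met[, j]))
    expect_lte(max(imp[, j]), max(ref_met[, j]))
  }
  expect_error(transfer_labels(ref_lip[, 0], ref_met, qry[, 0]), "empty")
  expect_error(transfer_labels(ref_lip, ref_met, qry[, 1:3]), "share")
})

test_that("transfer recovers per-phenotype metabolite means on synthetic data", {
  d <- simulate_msi_dataset(24, 24, 2, noise_sd = 0.02, seed = 43)
  norm <- tic_normalize(d$image)
  is_lip <- d$features$kind == "lipid"
  iso_glu <- d$features$kind == "isotopologue" &
    grepl("^glutamate", d$features$name)
  ref_lip <- norm$intensities[, is_lip, drop = FALSE]
  ref_met <- norm$intensities[, iso_glu, drop = FALSE]
  # hold out half the pixels as query
  set.seed(1)
  qi <- sample(nrow(ref_lip), nrow(ref_lip) %/% 2)
  imp <- transfer_labels(ref_lip[-qi, ], ref_met[-qi, ], ref_lip[qi, ], k = 10)
  lab_q <- d$truth$pixel_labels[qi]
  lab_r <- d$truth$pixel_labels[-qi]
  for (t in 1:2) {
    true_mean <- colMeans(ref_met[-qi, ][lab_r == t, , drop = FALSE])
    imp_mean <- colMeans(imp[lab_q == t, , drop = FALSE])
    big <- true_mean > 1e-4  # relative error meaningful on real signal only
    expect_lt(max(abs(imp_mean[big] / true_mean[big] - 1)), 0.05)
  }
})

test_that("adjusted Rand index behaves at its anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)
  set.seed(2)
  a <- sample(1:3, 3000, replace = TRUE)
  b <- sample(1:3, 3000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
})
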