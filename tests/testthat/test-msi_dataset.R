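# MSI data model, CSV I/O and preprocessing.

test_that("pixel CSV round-trip preserves coordinates and intensities", {
  img <- tiny_image()
  f <- withr::local_tempfile(fileext = ".csv")
  write_pixel_csv(img, f)
  back <- read_pixel_csv(f)
  expect_identical(back$coords, img$coords)
  expect_equal(back$mz, img$mz)
  expect_lt(max(abs(back$intensities - img$intensities)), 1e-9)

  # m/z columns arrive in file order but are sorted with the permutation
  # applied to intensities
  lines <- readLines(f)
  hdr <- strsplit(lines[1], ",")[[1]]
  perm <- c(1, 2, 5, 3, 4)  # shuffle the three m/z columns
  shuffled <- vapply(strsplit(lines, ","), function(p)
    paste(p[perm], collapse = ","), character(1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(shuffled, f2)
  back2 <- read_pixel_csv(f2)
  expect_equal(back2$mz, img$mz)
  expect_equal(back2$intensities, back$intensities, ignore_attr = TRUE)
})

test_that("pixel CSV format errors are caught and name the offender", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,400.5,500.5", "0,0,1,2", "0,0,3,4"), f)
  expect_error(read_pixel_csv(f), "duplicate pixel coordinate \\(0, 0\\)")
  writeLines(c("x,y,400.5,500.5", "0,0,1,-2"), f)
  expect_error(read_pixel_csv(f), "negative intensity")
  writeLines(c("x,y,400.5,500.5", "0,0,1"), f)
  expect_error(read_pixel_csv(f), "ragged|non-numeric|elements")
})

test_that("TIC normalization divides by pixel sums and drops zero pixels", {
  img <- spectral_image(cbind(x = 0:2, y = rep(0L, 3)), c(400, 500, 600),
                        rbind(c(2, 3, 5), c(0, 0, 0), c(1, 0, 0)))
  norm <- tic_normalize(img)
  expect_equal(attr(norm, "dropped_pixels"), 1L)
  expect_equal(nrow(norm$intensities), 2L)
  expect_equal(norm$intensities[1, ], c(0.2, 0.3, 0.5), ignore_attr = TRUE)
  expect_true(all(abs(rowSums(norm$intensities) - 1) < 1e-9))
  expect_true(norm$normalized)
  # idempotence on its own output (values unchanged by re-scaling)
  expect_true(all(abs(norm$intensities / rowSums(norm$intensities) -
                        norm$intensities) < 1e-12))
  expect_error(tic_normalize(norm), "already")
  all_zero <- spectral_image(cbind(x = 0L, y = 0L), c(400), matrix(0, 1, 1))
  expect_error(tic_normalize(all_zero), "zero total ion count")
})

test_that("count matrix floors 100x fractions into 0..100", {
  img <- spectral_image(cbind(x = 0:1, y = rep(0L, 2)), c(400, 500),
                        rbind(c(0.237, 0.763), c(0.0099, 0.9901)),
                        normalized = TRUE)
  cm <- to_count_matrix(img)
  expect_identical(cm[1, ], c(`400` = 23L, `500` = 76L))
  expect_identical(unname(cm[2, 1]), 0L)
  expect_true(all(cm >= 0 & cm <= 100))
  one_hot <- spectral_image(cbind(x = 0L, y = 0L), 400, matrix(1, 1, 1),
                            normalized = TRUE)
  expect_identical(unname(to_count_matrix(one_hot)[1, 1]), 100L)
  expect_error(to_count_matrix(tiny_image()), "normalized")
})

test_that("lipid feature selection filters on m/z, S/N and matrix flag", {
  img <- spectral_image(cbind(x = 0L, y = 0L), c(380, 500, 766.5, 810.5),
                        matrix(1, 1, 4))
  tab <- feature_table(mz = c(380, 500, 766.5, 810.5),
                       kind = c("lipid", "matrix", "lipid", "lipid"),
                       snr = c(10, 9, 5, 2))
  sel <- select_lipid_features(img, tab)
  expect_equal(sel$mz, 766.5)
  # all qualifying -> identity
  tab2 <- feature_table(mz = img$mz, kind = "lipid", snr = 10)
  expect_equal(select_lipid_features(img, tab2, min_mz = 100)$mz, img$mz)
  tab3 <- feature_table(mz = img$mz, kind = "matrix", snr = 10)
  expect_error(select_lipid_features(img, tab3), "no feature passes")
})

test_that("ppm annotation picks the closest reference within tolerance", {
  ref <- feature_table(mz = c(885.5499, 885.5723), name = c("PI 38:4", "PS"))
  hit <- annotate_features(885.549, ref)
  expect_equal(hit$name, "PI 38:4")
  expect_equal(hit$ppm_error, abs(885.549 - 885.5499) / 885.5499 * 1e6)
  expect_lt(hit$ppm_error, 1.1)
  miss <- annotate_features(885.570, ref, tol_ppm = 20)
  # 22.7 ppm from the first entry, but only 2.6 from the second
  expect_equal(abs(885.570 - 885.5499) / 885.5499 * 1e6, 22.70, tolerance = 1e-3)
  expect_equal(miss$name, "PS")
  lone <- feature_table(mz = 885.5499, name = "PI 38:4")
  expect_true(is.na(annotate_features(885.570, lone)$ref_index))
  exact <- annotate_features(885.5499, lone)
  expect_equal(exact$ppm_error, 0)
  # exact tie between two candidates (isobars) -> ambiguous, unmatched
  twin <- feature_table(mz = c(500.002, 500.002), name = c("a", "b"))
  amb <- annotate_features(500, twin)
  expect_true(amb$ambiguous)
  expect_true(is.na(amb$ref_index))
})

test_that("annotation commutes with feature reordering after selection", {
  img <- spectral_image(cbind(x = 0L, y = 0L), c(420.1, 640.2, 880.3),
                        matrix(c(1, 2, 3), 1))
  tab <- feature_table(mz = img$mz, kind = "lipid", snr = c(5, 7, 9))
  ref <- feature_table(mz = c(420.1001, 880.3002), name = c("A", "B"))
  a <- annotate_features(select_lipid_features(img, tab)$mz, ref)
  expect_equal(a$name[!is.na(a$name)], c("A", "B"))
})

test_that("hotspot clipping caps at the interpolated 99% quantile", {
  v <- as.numeric(1:100)
  clipped <- hotspot_clip(v, 0.99)
  q99 <- stats::quantile(v, 0.99, names = FALSE)  # 99.01 under type 7
  expect_equal(max(clipped), q99)
  expect_equal(clipped[1:98], v[1:98])
  expect_equal(hotspot_clip(rep(3, 10)), rep(3, 10))
  expect_error(hotspot_clip(v, 1.0), "quantile")
  expect_error(hotspot_clip(v, 0), "quantile")
})

test_that("dataset stats reproduce pixel and area bookkeeping", {
  s <- dataset_stats(total_pixels = 2394033, n_sections = 33)
  expect_equal(s$mean_pixels_per_section, 72546)
  expect_equal(s$mean_area_mm2, 1.8)
  tinystats <- dataset_stats(images = list(
    spectral_image(cbind(x = c(0:1, 0:1), y = c(0, 0, 1, 1)), 400,
                   matrix(1, 4, 1))))
  expect_equal(tinystats$area_mm2_per_section, 4 * 25e-6)
  expect_error(dataset_stats(images = list()), "empty")
})
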