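# Synthetic tissue, forward flux model, rendering, perfusion series.

test_that("tissue generator labels every pixel with contiguous regions", {
  lab <- generate_tissue(8, 8, 2, seed = 1)
  expect_equal(dim(lab), c(8, 8))
  expect_true(all(lab %in% 1:2))
  expect_setequal(unique(as.integer(lab)), 1:2)

  expect_identical(generate_tissue(12, 10, 3, seed = 7),
                   generate_tissue(12, 10, 3, seed = 7))

  lab4 <- generate_tissue(64, 64, 4, seed = 3)
  occupancy <- table(lab4) / length(lab4)
  expect_true(all(occupancy >= 0.01))

  expect_error(generate_tissue(4, 8, 2), "width")
  expect_error(generate_tissue(8, 8, 1), "n_types")
  expect_error(generate_tissue(8, 8, 9), "n_types")
})

test_that("forward flux model inverts the ratio definitions", {
  e <- forward_isotopologues(identity_ratios, gln_m5 = 0.5)
  expect_equal(e$glutamate[6], 0.5)
  expect_equal(e$succinate[5], 0.5)
  expect_equal(e$malate[5], 0.5)

  e2 <- forward_isotopologues(c(gls_ogdh = 0.5, ogdh_sdhf = 1, sdhf_mdh = 1),
                              gln_m5 = 0.8)
  expect_equal(e2$glutamate[6], 0.4)

  e3 <- forward_isotopologues(c(gls_ogdh = 0.6, ogdh_sdhf = 0.7,
                                sdhf_mdh = 0.9), gln_m5 = 0.9)
  expect_equal(e3$malate[5], 0.9 * 0.7 * 0.6 * 0.9)  # 0.3402

  # every fraction vector sums to 1 within 1e-9; residual mass in M+0
  for (v in e3) {
    expect_lt(abs(sum(v) - 1), 1e-9)
    expect_equal(v[1], 1 - max(v[-1]))
  }

  expect_error(forward_isotopologues(c(gls_ogdh = 2, ogdh_sdhf = 1,
                                       sdhf_mdh = 1), gln_m5 = 0.8),
               "infeasible")
  expect_error(forward_isotopologues(c(gls_ogdh = -1, ogdh_sdhf = 1,
                                       sdhf_mdh = 1)), "finite and > 0")
})

test_that("noiseless rendering gives identical within-phenotype spectra", {
  d <- noiseless_dataset(n_types = 2, seed = 5)
  norm <- tic_normalize(d$image)
  lab <- d$truth$pixel_labels
  for (t in 1:2) {
    px <- norm$intensities[lab == t, , drop = FALSE]
    expect_lt(max(abs(sweep(px, 2, px[1, ]))), 1e-12)
  }
})

test_that("with p13c=0 and purity=1 observed channels equal true enrichments", {
  labels <- generate_tissue(8, 8, 2, seed = 2)
  enr <- list(forward_isotopologues(identity_ratios, gln_m5 = 0.5),
              forward_isotopologues(c(gls_ogdh = 0.8, ogdh_sdhf = 0.9,
                                      sdhf_mdh = 0.7), gln_m5 = 0.5))
  d <- render_dataset(labels, NULL, enr, noise_sd = 0, tic_cv = 0,
                      p13c = 0, tracer_purity = 1, seed = 2)
  per_px <- pixel_enrichments(tic_normalize(d$image), d$features,
                              p13c = 0, tracer_purity = 1)
  px1 <- which(d$truth$pixel_labels == 1)[1]
  expect_equal(unname(per_px$glutamate[px1, ]), enr[[1]]$glutamate,
               tolerance = 1e-9)
  expect_equal(unname(per_px$malate[px1, ]), enr[[1]]$malate,
               tolerance = 1e-9)
})

test_that("rendered isotopologue channels carry the binomial forward mixture", {
  # unlabeled 2-carbon check of the renderer's convolution, against the
  # closed-form binomial: (1-p)^2, 2p(1-p), p^2
  m <- build_forward_matrix(2, p13c = 0.0107, tracer_purity = 1)
  obs <- apply_forward(m, c(1, 0, 0))
  expect_equal(obs, c(0.97871, 0.02117, 0.00011), tolerance = 5e-5)
})

test_that("rendering is deterministic and validates arguments", {
  a <- simulate_msi_dataset(8, 8, 2, seed = 9)
  b <- simulate_msi_dataset(8, 8, 2, seed = 9)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$truth$true_flux_ratios, b$truth$true_flux_ratios)
  labels <- generate_tissue(8, 8, 3, seed = 1)
  expect_error(render_dataset(labels, NULL,
                              list(forward_isotopologues(identity_ratios))),
               "one metabolite enrichment set per phenotype")
})

test_that("ground truth JSON export round-trips the ratio targets", {
  d <- simulate_msi_dataset(8, 8, 2, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(d$truth, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$p13c, 0.0107)
  expect_equal(back$tracer_purity, 0.99)
  tv <- d$truth$true_flux_ratios[[1]]
  bv <- back$true_flux_ratios[[1]]
  for (k in names(tv)[!is.na(tv)]) {
    expect_equal(bv[[k]], unname(tv[[k]]), tolerance = 1e-12)
  }
})

test_that("perfusion series shows plateau, failure decline and determinism", {
  stable <- generate_perfusion_timeseries(4, seed = 3)
  # plateau: daily means after the first ramp stay within a few percent
  day_mean <- tapply(stable$flow_ml_min, floor(stable$time_h / 24), mean)
  expect_lt(max(abs(day_mean[-1] / mean(day_mean[-1]) - 1)), 0.05)

  failing <- generate_perfusion_timeseries(8, failure_day = 4, seed = 3)
  early <- mean(failing$flow_ml_min[failing$time_h < 4 * 24])
  late <- mean(failing$flow_ml_min[failing$time_h >= 4 * 24])
  expect_lt(late, early)

  expect_identical(generate_perfusion_timeseries(4, seed = 8),
                   generate_perfusion_timeseries(4, seed = 8))
  expect_error(generate_perfusion_timeseries(4, failure_day = 6), "exceeds")
  expect_error(generate_perfusion_timeseries(0), "days")
})
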