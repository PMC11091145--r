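# End-to-end orchestration: simulate (or load) -> preprocess -> segment ->
# correct -> enrich -> flux ratios -> physiology -> report.

#' Pipeline configuration
#'
#' Assembles and validates the flat key-value configuration driving
#' [run_pipeline()]. All randomness downstream is derived deterministically
#' from the single `seed`, so identical configurations produce
#' byte-identical report bodies.
#'
#' @param seed master integer seed.
#' @param width,height,n_types synthetic tissue dimensions and phenotype
#'   count (ignored when `input_csv` is supplied).
#' @param noise_sd,tic_cv synthetic noise parameters.
#' @param p13c,tracer_purity isotope-correction parameters.
#' @param min_mz,min_snr lipid feature selection thresholds.
#' @param n_clusters number of pixel clusters (default `n_types`).
#' @param k_transfer neighbours for metabolite transfer (reserved for
#'   two-dataset runs).
#' @param quantile hotspot-removal quantile.
#' @param baseline_cluster cluster id used as fold-change baseline.
#' @param days,failure_day perfusion simulation horizon.
#' @param input_csv,features_tsv optional real-data inputs replacing the
#'   simulator (pixel CSV dialect + feature TSV).
#' @param out_dir optional directory for intermediate artifacts and the
#'   report files.
#' @return validated config list of class `msi_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, width = 64, height = 64, n_types = 3,
                            noise_sd = 0.05, tic_cv = 0.2, p13c = 0.0107,
                            tracer_purity = 0.99, min_mz = 400, min_snr = 3,
                            n_clusters = n_types, k_transfer = 10,
                            quantile = 0.99, baseline_cluster = 1L,
                            days = 4, failure_day = NULL,
                            input_csv = NULL, features_tsv = NULL,
                            out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), width = width, height = height,
              n_types = n_types, noise_sd = noise_sd, tic_cv = tic_cv,
              p13c = p13c, tracer_purity = tracer_purity, min_mz = min_mz,
              min_snr = min_snr, n_clusters = n_clusters,
              k_transfer = k_transfer, quantile = quantile,
              baseline_cluster = baseline_cluster, days = days,
              failure_day = failure_day, input_csv = input_csv,
              features_tsv = features_tsv, out_dir = out_dir)
  if (cfg$noise_sd < 0 || cfg$tic_cv < 0) stop_arg("noise levels must be >= 0")
  if (cfg$p13c < 0 || cfg$p13c >= 0.5) stop_arg("p13c must lie in [0, 0.5)")
  if (cfg$tracer_purity <= 0 || cfg$tracer_purity > 1) {
    stop_arg("tracer_purity must lie in (0, 1]")
  }
  if (cfg$quantile <= 0 || cfg$quantile >= 1) stop_arg("quantile must be in (0, 1)")
  if (cfg$n_clusters < 2) stop_arg("n_clusters must be >= 2")
  class(cfg) <- "msi_pipeline_config"
  cfg
}

#' Run the full spatial isotope-tracing pipeline
#'
#' Executes every stage in order on either a synthetic dataset (default) or
#' a supplied pixel CSV: TIC normalization, lipid feature selection,
#' phenotype clustering with marker annotation, per-pixel isotope correction
#' and fraction enrichment, cluster summaries with fold changes, relative
#' TCA flux ratios per cluster, and a simulated perfusion-physiology
#' summary. Intermediate artifacts and a JSON + Markdown report are written
#' when `out_dir` is set.
#'
#' @param config a [pipeline_config()] (or list of its arguments).
#' @return object of class `msi_pipeline_report`: named list with
#'   `composition`, `annotation`, `enrichment`, `flux` (per-cluster
#'   [compute_flux_set()] results), `physiology`, `truth` (synthetic runs
#'   only), and `json` (the canonical report body as a JSON string).
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 1, width = 24, height = 24,
#'                                     n_types = 2))
#' rep$flux[[1]]
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "msi_pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  # --- acquire data -------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input_csv)) {
    dat <- stage("load", {
      if (!file.exists(config$input_csv)) {
        stop_arg("input path not found: %s", config$input_csv)
      }
      if (is.null(config$features_tsv) || !file.exists(config$features_tsv)) {
        stop_arg("feature table path not found: %s",
                 config$features_tsv %||% "(not set)")
      }
      list(image = read_pixel_csv(config$input_csv),
           features = read_feature_table(config$features_tsv))
    })
  } else {
    dat <- stage("simulate", simulate_msi_dataset(
      width = config$width, height = config$height, n_types = config$n_types,
      noise_sd = config$noise_sd, tic_cv = config$tic_cv, p13c = config$p13c,
      tracer_purity = config$tracer_purity,
      seed = derive_seed(config$seed, "simulate")))
    truth <- dat$truth
    if (!is.null(out_dir)) {
      write_pixel_csv(dat$image, file.path(out_dir, "pixels.csv"))
      write_feature_table(dat$features, file.path(out_dir, "features.tsv"))
      write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
    }
  }

  # --- preprocess ---------------------------------------------------------
  norm <- stage("preprocess", tic_normalize(dat$image))
  keep_px <- rowSums(dat$image$intensities) > 0
  lipids <- stage("preprocess", select_lipid_features(
    norm, dat$features, min_mz = config$min_mz, min_snr = config$min_snr))
  lipid_names <- dat$features$name[attr(lipids, "kept")]

  # --- segment ------------------------------------------------------------
  map <- stage("segment", cluster_pixels(
    lipids, n_clusters = config$n_clusters,
    seed = derive_seed(config$seed, "segment")))
  if (is.null(config$input_csv)) {
    markers <- stats::setNames(
      as.list(paste0("lipid_", seq_len(config$n_types))),
      paste0("type", seq_len(config$n_types)))
    map <- stage("segment", annotate_clusters(map, lipids, markers,
                                              feature_names = lipid_names))
  }
  comp <- as.data.frame(table(cluster = map$pixel_cluster),
                        responseName = "pixels")
  comp$fraction <- comp$pixels / sum(comp$pixels)

  # --- correct + enrich ---------------------------------------------------
  per_pixel <- stage("correct", pixel_enrichments(
    norm, dat$features, p13c = config$p13c,
    tracer_purity = config$tracer_purity))
  per_cluster <- stage("enrich", summarize_by_cluster(per_pixel, map))
  per_cluster <- stage("enrich", log2fc_vs_baseline(
    per_cluster, baseline = config$baseline_cluster))

  # --- flux ratios --------------------------------------------------------
  flux <- stage("qflux", {
    lapply(sort(unique(per_cluster$cluster)), function(c_id) {
      g <- function(m, k) {
        r <- per_cluster$cluster == c_id & per_cluster$metabolite == m &
          per_cluster$k == k
        if (!any(r)) NA_real_ else per_cluster$mean[r]
      }
      compute_flux_set(c(gln_m5 = g("glutamine", 5), glu_m5 = g("glutamate", 5),
                         succ_m4 = g("succinate", 4), mal_m4 = g("malate", 4)))
    })
  })
  names(flux) <- paste0("cluster_", sort(unique(per_cluster$cluster)))

  # --- physiology ---------------------------------------------------------
  phys <- stage("physiology", {
    ts <- generate_perfusion_timeseries(
      days = config$days, failure_day = config$failure_day,
      seed = derive_seed(config$seed, "physiology"))
    summarize_perfusion(ts)
  })

  report <- list(
    config = config[setdiff(names(config), "out_dir")],
    composition = comp,
    annotation = if (length(map$annotation)) {
      data.frame(cluster = seq_along(map$annotation),
                 phenotype = map$annotation)
    } else NULL,
    enrichment = per_cluster,
    flux = flux,
    physiology = list(daily = phys$daily, weight_gain = phys$weight_gain),
    truth = if (!is.null(truth)) {
      list(true_flux_ratios = truth$true_flux_ratios)
    } else NULL
  )
  report$json <- report_json(report)
  class(report) <- "msi_pipeline_report"

  if (!is.null(out_dir)) {
    writeLines(report$json, file.path(out_dir, "report.json"))
    writeLines(report_markdown(report), file.path(out_dir, "report.md"))
    utils::write.csv(per_cluster, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(x = map$coords[, "x"], y = map$coords[, "y"],
                 cluster = map$pixel_cluster,
                 phenotype = if (length(map$annotation)) {
                   map$annotation[map$pixel_cluster]
                 } else NA_character_),
      file.path(out_dir, "clusters.csv"), row.names = FALSE)
  }
  report$map <- map
  report$per_pixel <- per_pixel
  report$image <- norm
  report$features <- dat$features
  if (!is.null(truth)) report$ground_truth <- truth
  invisible(report)
}

# Canonical (timestamp-free) JSON body of a report.
report_json <- function(report) {
  body <- report[c("config", "composition", "annotation", "enrichment",
                   "physiology", "truth")]
  body$flux <- lapply(report$flux, function(fs) {
    vals <- fs[c("v_gls_over_ogdh", "v_gls_over_idh", "v_ogdh_over_sdhf",
                 "v_sdhf_over_mdh")]
    lapply(vals, function(v) {
      if (is_valid_ratio(v)) as.numeric(v) else
        list(invalid = TRUE, reason = attr(v, "reason") %||% "missing input")
    })
  })
  body$config <- Filter(Negate(is.null), unclass(body$config))
  jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   na = "null")
}

report_markdown <- function(report) {
  ln <- c("# Spatial isotope-tracing pipeline report", "",
          sprintf("Seed: %d", report$config$seed), "",
          "## Cluster composition", "")
  for (i in seq_len(nrow(report$composition))) {
    r <- report$composition[i, ]
    ph <- if (!is.null(report$annotation)) {
      sprintf(" (%s)", report$annotation$phenotype[i])
    } else ""
    ln <- c(ln, sprintf("- cluster %s%s: %d pixels (%.1f%%)",
                        r$cluster, ph, r$pixels, 100 * r$fraction))
  }
  ln <- c(ln, "", "## Relative TCA flux ratios", "")
  for (nm in names(report$flux)) {
    fs <- report$flux[[nm]]
    fmt <- function(v) if (is_valid_ratio(v)) sprintf("%.4f", v) else "invalid"
    ln <- c(ln, sprintf("- %s: V_GLS/V_OGDH=%s, V_GLS/V_IDH=%s, V_OGDH/V_SDH(F)=%s, V_SDH(F)/V_MDH=%s",
                        nm, fmt(fs$v_gls_over_ogdh), fmt(fs$v_gls_over_idh),
                        fmt(fs$v_ogdh_over_sdhf), fmt(fs$v_sdhf_over_mdh)))
  }
  if (!is.null(report$physiology$weight_gain)) {
    ln <- c(ln, "", sprintf("Weight gain: %d%%",
                            as.integer(report$physiology$weight_gain$percent_int)))
  }
  ln
}

#' @export
print.msi_pipeline_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

#' Match annotated clusters to ground-truth phenotypes
#'
#' For synthetic runs: returns the per-phenotype flux-ratio sets keyed by
#' the generator's phenotype ids, using the cluster annotation. Unannotated
#' clusters are skipped.
#'
#' @param report a [run_pipeline()] result from a synthetic run.
#' @return named list phenotype id -> `flux_ratio_set`.
#' @export
flux_by_phenotype <- function(report) {
  stopifnot(inherits(report, "msi_pipeline_report"))
  if (is.null(report$annotation)) stop_arg("report has no cluster annotation")
  out <- list()
  for (i in seq_len(nrow(report$annotation))) {
    ph <- report$annotation$phenotype[i]
    if (!is.na(ph)) out[[ph]] <- report$flux[[paste0("cluster_", i)]]
  }
  out
}
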