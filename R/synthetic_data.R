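# Synthetic MSI datasets with known ground truth, built from a forward flux
# model, so every downstream stage is testable without external data.

# Canonical metabolites carried by the glutamine-tracer forward model.
QFLUX_METABOLITES <- c(glutamine = 5L, glutamate = 5L,
                       succinate = 4L, malate = 4L)

# Base abundances (arbitrary units) for metabolite channels before TIC
# variation; rough tissue-like relative pool sizes.
METABOLITE_BASE <- c(glutamine = 80, glutamate = 100,
                     succinate = 60, malate = 60)

#' Generate a blob-like tissue phenotype map
#'
#' Grows `n_types` contiguous regions from random seed pixels by repeated
#' frontier expansion (a seeded multi-source flood fill), emulating the
#' contiguous tubular cross-sections seen in kidney cortex segmentations.
#' Every pixel receives exactly one label; output is deterministic for a
#' fixed seed.
#'
#' @param width,height grid dimensions in pixels, both >= 8.
#' @param n_types number of phenotype regions, 2..8.
#' @param seed integer RNG seed.
#' @return integer matrix `height` x `width` of phenotype labels in
#'   `1..n_types`.
#' @examples
#' table(generate_tissue(16, 16, 3, seed = 1))
#' @export
generate_tissue <- function(width, height, n_types, seed = 1L) {
  if (width < 8 || height < 8) stop_arg("width and height must be >= 8")
  if (n_types < 2 || n_types > 8) stop_arg("n_types must be in 2..8")
  with_seed(seed, {
    lab <- matrix(0L, nrow = height, ncol = width)
    centers <- cbind(row = sample.int(height, n_types, replace = FALSE),
                     col = sample.int(width, n_types, replace = FALSE))
    frontier <- vector("list", n_types)
    for (t in seq_len(n_types)) {
      lab[centers[t, 1], centers[t, 2]] <- t
      frontier[[t]] <- centers[t, , drop = FALSE]
    }
    n_left <- height * width - n_types
    while (n_left > 0L) {
      # expand each region's frontier in random type order for organic shapes
      for (t in sample.int(n_types)) {
        fr <- frontier[[t]]
        if (nrow(fr) == 0L) next
        new_cells <- NULL
        for (i in sample.int(nrow(fr))) {
          r <- fr[i, 1]; cc <- fr[i, 2]
          nb <- rbind(c(r - 1L, cc), c(r + 1L, cc), c(r, cc - 1L), c(r, cc + 1L))
          nb <- nb[nb[, 1] >= 1 & nb[, 1] <= height &
                   nb[, 2] >= 1 & nb[, 2] <= width, , drop = FALSE]
          free <- nb[lab[nb] == 0L, , drop = FALSE]
          if (nrow(free) > 0L) {
            pick <- free[sample.int(nrow(free), 1L), , drop = FALSE]
            lab[pick] <- t
            n_left <- n_left - 1L
            new_cells <- rbind(new_cells, pick)
            if (n_left == 0L) break
          }
        }
        # keep only frontier cells that can still grow
        fr <- rbind(fr, new_cells)
        can_grow <- vapply(seq_len(nrow(fr)), function(i) {
          r <- fr[i, 1]; cc <- fr[i, 2]
          nb <- rbind(c(r - 1L, cc), c(r + 1L, cc), c(r, cc - 1L), c(r, cc + 1L))
          nb <- nb[nb[, 1] >= 1 & nb[, 1] <= height &
                   nb[, 2] >= 1 & nb[, 2] <= width, , drop = FALSE]
          any(lab[nb] == 0L)
        }, logical(1))
        frontier[[t]] <- fr[can_grow, , drop = FALSE]
        if (n_left == 0L) break
      }
    }
    lab
  })
}

#' Forward-model isotopologue enrichments from target flux ratios
#'
#' Inverts the glutamine-tracer flux-ratio definitions to construct a set of
#' true fraction-enrichment vectors that, passed through the flux-ratio
#' computation after perfect correction, reproduce the target ratios
#' exactly. The chain is: glutamate(m+5) = ratio_gls_ogdh x glutamine(m+5);
#' succinate(m+4) = ratio_ogdh_sdhf x glutamate(m+5);
#' malate(m+4) = ratio_sdhf_mdh x succinate(m+4). The GLS/IDH ratio is not a
#' free parameter — it is determined by the GLS/OGDH ratio as r/(1-r).
#' Residual pool mass is assigned to M+0.
#'
#' @param true_flux_ratios named vector/list with `gls_ogdh`, `ogdh_sdhf`,
#'   `sdhf_mdh` (positive reals).
#' @param gln_m5 true glutamine M+5 fraction enrichment — the fraction of
#'   the tissue glutamine pool replaced by tracer (default 0.25).
#' @return named list of true fraction vectors (length n+1 per metabolite),
#'   one per metabolite in `c("glutamine", "glutamate", "succinate",
#'   "malate")`; attribute `ratios` stores the implied four-ratio set.
#' @examples
#' e <- forward_isotopologues(c(gls_ogdh = 1, ogdh_sdhf = 1, sdhf_mdh = 1),
#'                            gln_m5 = 0.5)
#' e$malate
#' @export
forward_isotopologues <- function(true_flux_ratios, gln_m5 = 0.25) {
  r <- as.list(true_flux_ratios)
  need <- c("gls_ogdh", "ogdh_sdhf", "sdhf_mdh")
  if (!all(need %in% names(r))) {
    stop_arg("true_flux_ratios needs entries %s", paste(need, collapse = ", "))
  }
  vals <- unlist(r[need])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_arg("flux ratios must be finite and > 0")
  }
  if (gln_m5 <= 0 || gln_m5 >= 1) stop_arg("gln_m5 must lie in (0, 1)")
  glu_m5 <- r$gls_ogdh * gln_m5
  succ_m4 <- r$ogdh_sdhf * glu_m5
  mal_m4 <- r$sdhf_mdh * succ_m4
  implied <- c(glutamine = gln_m5, glutamate = glu_m5,
               succinate = succ_m4, malate = mal_m4)
  if (any(implied >= 1) || any(implied <= 0)) {
    stop_arg("infeasible flux ratios: implied enrichment outside (0, 1) [%s]",
             paste(sprintf("%s=%.3f", names(implied), implied), collapse = ", "))
  }
  out <- list()
  for (m in names(QFLUX_METABOLITES)) {
    n <- QFLUX_METABOLITES[[m]]
    v <- rep(0, n + 1L)
    k <- if (n == 5L) 5L else 4L  # labeled channel: m+5 (5C) or m+4 (4C)
    v[k + 1L] <- implied[[m]]
    v[1L] <- 1 - implied[[m]]
    out[[m]] <- v
  }
  # GLS/IDH is implied by GLS/OGDH (= the glutamine-derived fraction r of
  # the alpha-KG pool): r/(1-r), undefined when r >= 1.
  r1 <- unname(r$gls_ogdh)
  attr(out, "ratios") <- c(
    gls_ogdh = r1,
    gls_idh = if (r1 < 1) r1 / (1 - r1) else NA_real_,
    ogdh_sdhf = unname(r$ogdh_sdhf),
    sdhf_mdh = unname(r$sdhf_mdh)
  )
  out
}

# Default lipid signatures: base lognormal levels shared across phenotypes
# plus one dominant marker lipid per phenotype (5x elevated), so marker-based
# cluster annotation has a clean surrogate for immunostaining.
default_lipid_signatures <- function(n_types, n_lipids = max(8L, 2L * n_types),
                                     seed = 1L) {
  with_seed(seed + 211L, {
    base <- matrix(stats::rlnorm(n_types * n_lipids, meanlog = 3, sdlog = 0.4),
                   nrow = n_types)
    for (t in seq_len(n_types)) base[t, t] <- base[t, t] * 5
    rownames(base) <- paste0("type", seq_len(n_types))
    colnames(base) <- paste0("lipid_", seq_len(n_lipids))
    base
  })
}

# m/z grid for synthetic features: lipids spread over 700-900, isotopologue
# channels at the metabolite monoisotopic mass + k * 1.00336 (13C-12C shift).
synthetic_feature_table <- function(n_lipids) {
  mono <- c(glutamine = 145.0619, glutamate = 146.0459,
            succinate = 117.0193, malate = 133.0142)  # [M-H]- masses
  rows <- list()
  for (m in names(QFLUX_METABOLITES)) {
    n <- QFLUX_METABOLITES[[m]]
    for (k in 0:n) {
      rows[[length(rows) + 1L]] <- data.frame(
        mz = mono[[m]] + k * 1.00336,
        name = sprintf("%s_M%d", m, k), n_carbons = n,
        kind = "isotopologue", snr = 20, isotopologue_index = k)
    }
  }
  lip_mz <- seq(700.5, 900.5, length.out = n_lipids)
  for (i in seq_len(n_lipids)) {
    rows[[length(rows) + 1L]] <- data.frame(
      mz = lip_mz[i], name = paste0("lipid_", i), n_carbons = NA_integer_,
      kind = "lipid", snr = 15, isotopologue_index = NA_integer_)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$mz), ]
  rownames(df) <- NULL
  feature_table(df$mz, df$name, df$n_carbons, df$kind, df$snr,
                df$isotopologue_index)
}

#' Render a synthetic spectral image with ground truth
#'
#' Produces the pixel-by-feature matrix a MALDI-TOF export would yield for
#' the given tissue map: per-pixel intensity = phenotype signature x a
#' log-normal TIC factor plus additive Gaussian noise truncated at zero.
#' Isotopologue channels carry the phenotype's true enrichment vectors
#' convolved with the natural-abundance/tracer-purity forward model before
#' noise, so the observed data require correction just as real data do.
#'
#' @param labels phenotype label matrix from [generate_tissue()].
#' @param lipid_signatures matrix `n_types` x n_lipids of lipid base
#'   intensities, or NULL for [default_lipid_signatures()].
#' @param metabolite_enrichments list of per-phenotype enrichment sets, each
#'   from [forward_isotopologues()]; length must equal the number of
#'   phenotypes.
#' @param noise_sd additive noise scale as a fraction of each channel's
#'   clean intensity (default 0.05).
#' @param tic_cv coefficient of variation of the per-pixel log-normal TIC
#'   factor (default 0.2).
#' @param p13c natural 13C abundance used in the forward convolution.
#' @param tracer_purity tracer purity used in the forward convolution.
#' @param seed integer RNG seed.
#' @return list with `image` (raw, unnormalized [spectral_image()]),
#'   `features` ([feature_table()]), and `truth` (class `ground_truth`:
#'   `pixel_labels`, `true_flux_ratios` per phenotype, `true_enrichments`,
#'   `tracer_purity`, `p13c`, `seed`).
#' @export
render_dataset <- function(labels, lipid_signatures = NULL,
                           metabolite_enrichments, noise_sd = 0.05,
                           tic_cv = 0.2, p13c = 0.0107, tracer_purity = 0.99,
                           seed = 1L) {
  if (noise_sd < 0 || tic_cv < 0) stop_arg("noise_sd and tic_cv must be >= 0")
  n_types <- max(labels)
  if (is.null(lipid_signatures)) {
    lipid_signatures <- default_lipid_signatures(n_types, seed = seed)
  }
  if (nrow(lipid_signatures) != n_types) {
    stop_arg("lipid_signatures has %d rows but labels carry %d phenotypes",
             nrow(lipid_signatures), n_types)
  }
  if (length(metabolite_enrichments) != n_types) {
    stop_arg("need one metabolite enrichment set per phenotype")
  }
  n_lipids <- ncol(lipid_signatures)
  features <- synthetic_feature_table(n_lipids)

  # forward-convolve each phenotype's true enrichments once
  models <- lapply(QFLUX_METABOLITES, function(n) {
    build_forward_matrix(n, p13c = p13c, tracer_purity = tracer_purity)
  })
  observed_iso <- lapply(seq_len(n_types), function(t) {
    lapply(names(QFLUX_METABOLITES), function(m) {
      apply_forward(models[[m]], metabolite_enrichments[[t]][[m]])
    }) |> stats::setNames(names(QFLUX_METABOLITES))
  })

  # clean per-phenotype spectrum over the full (sorted) feature set
  clean <- matrix(0, nrow = n_types, ncol = nrow(features))
  for (t in seq_len(n_types)) {
    for (j in seq_len(nrow(features))) {
      f <- features[j, ]
      if (f$kind == "lipid") {
        idx <- as.integer(sub("lipid_", "", f$name))
        clean[t, j] <- lipid_signatures[t, idx]
      } else {
        m <- sub("_M\\d+$", "", f$name)
        k <- f$isotopologue_index
        clean[t, j] <- METABOLITE_BASE[[m]] * observed_iso[[t]][[m]][k + 1L]
      }
    }
  }

  h <- nrow(labels); w <- ncol(labels)
  px_labels <- as.integer(t(labels))      # row-major pixel order
  coords <- cbind(x = rep(0:(w - 1L), times = h),
                  y = rep(0:(h - 1L), each = w))
  with_seed(seed, {
    tic_sdlog <- sqrt(log(1 + tic_cv^2))
    tic <- stats::rlnorm(length(px_labels), meanlog = -tic_sdlog^2 / 2,
                         sdlog = tic_sdlog)
    inten <- clean[px_labels, , drop = FALSE] * tic
    if (noise_sd > 0) {
      noise <- matrix(stats::rnorm(length(inten), sd = 1),
                      nrow = nrow(inten)) * (noise_sd * inten)
      inten <- pmax(inten + noise, 0)
    }
    image <- spectral_image(coords, features$mz, inten)
    truth <- structure(
      list(pixel_labels = px_labels,
           label_grid = labels,
           true_flux_ratios = lapply(metabolite_enrichments,
                                     function(e) attr(e, "ratios")),
           true_enrichments = lapply(metabolite_enrichments, function(e) {
             e[names(QFLUX_METABOLITES)]
           }),
           tracer_purity = tracer_purity, p13c = p13c,
           noise_sd = noise_sd, tic_cv = tic_cv, seed = seed),
      class = "ground_truth")
    list(image = image, features = features, truth = truth)
  })
}

#' One-call synthetic MSI dataset
#'
#' Convenience wrapper: tissue map, per-phenotype flux ratios, forward
#' enrichments and rendering in one step.
#'
#' @param width,height grid size in pixels.
#' @param n_types number of phenotypes.
#' @param true_flux_ratios list of named ratio vectors (one per phenotype;
#'   recycled if a single set is given), or NULL to draw each ratio
#'   uniformly from `ratio_range`.
#' @param ratio_range range for randomly drawn ratios (default `c(0.5, 1.5)`).
#' @param gln_m5 true glutamine M+5 enrichment (default 0.25).
#' @param noise_sd,tic_cv,p13c,tracer_purity,seed passed to
#'   [render_dataset()].
#' @return as [render_dataset()].
#' @examples
#' d <- simulate_msi_dataset(16, 16, 2, seed = 1)
#' d$image
#' @export
simulate_msi_dataset <- function(width = 64, height = 64, n_types = 3,
                                 true_flux_ratios = NULL,
                                 ratio_range = c(0.5, 1.5), gln_m5 = 0.25,
                                 noise_sd = 0.05, tic_cv = 0.2,
                                 p13c = 0.0107, tracer_purity = 0.99,
                                 seed = 1L) {
  labels <- generate_tissue(width, height, n_types, seed = seed)
  if (is.null(true_flux_ratios)) {
    true_flux_ratios <- with_seed(seed + 17L, {
      lapply(seq_len(n_types), function(t) {
        c(gls_ogdh = stats::runif(1, ratio_range[1], ratio_range[2]),
          ogdh_sdhf = stats::runif(1, ratio_range[1], ratio_range[2]),
          sdhf_mdh = stats::runif(1, ratio_range[1], ratio_range[2]))
      })
    })
  } else if (!is.list(true_flux_ratios[[1]]) && !is.null(names(true_flux_ratios))) {
    true_flux_ratios <- rep(list(true_flux_ratios), n_types)
  }
  enr <- lapply(true_flux_ratios, forward_isotopologues, gln_m5 = gln_m5)
  render_dataset(labels, NULL, enr, noise_sd = noise_sd, tic_cv = tic_cv,
                 p13c = p13c, tracer_purity = tracer_purity, seed = seed)
}

#' Write ground truth to JSON
#'
#' @param truth a `ground_truth` object.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- truth
  out$label_grid <- NULL
  out$true_flux_ratios <- lapply(out$true_flux_ratios, as.list)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Generate a synthetic perfusion time series
#'
#' Smooth parametric hemodynamic curves with reproducible noise: renal flow
#' plateaus near 400 mL/min at a 75 mmHg pressure set-point and declines
#' after `failure_day`; arterial pO2 stays near carbogen saturation while
#' the arterio-venous difference shrinks as oxygen uptake falls; lactate
#' rises and pH drifts down after failure. Initial and final graft weights
#' emulate the edema-driven weight gain of multi-day perfusion.
#'
#' @param days duration in days (>= 1); sampled hourly.
#' @param failure_day day after which function deteriorates, or NULL for a
#'   stable run.
#' @param seed integer RNG seed.
#' @param noise_rel relative noise on the smooth curves (default 0.02).
#' @return data.frame of class `perfusion_timeseries` with columns
#'   `time_h`, `flow_ml_min`, `map_mmhg`, `po2_art`, `po2_ven`, `ph`,
#'   `lactate_mmol_l`, `glucose_mmol_l`; attributes `weight_initial_g`,
#'   `weight_final_g`.
#' @export
generate_perfusion_timeseries <- function(days, failure_day = NULL, seed = 1L,
                                          noise_rel = 0.02) {
  if (days < 1) stop_arg("days must be >= 1")
  if (!is.null(failure_day) && failure_day > days) {
    stop_arg("failure_day (%s) exceeds days (%s)", failure_day, days)
  }
  with_seed(seed, {
    t_h <- seq(0, days * 24)
    t_d <- t_h / 24
    fail <- function(rate) {
      if (is.null(failure_day)) rep(0, length(t_d))
      else pmax(0, t_d - failure_day) * rate
    }
    flow <- 400 * (1 - 0.25 * exp(-t_d / 0.1)) * exp(-fail(0.15))
    po2_art <- rep(600, length(t_d))
    uptake_target <- 1.0 * exp(-fail(0.5))  # mL O2/min
    po2_ven <- po2_art - uptake_target / (0.0031 * flow / 100)
    ph <- 7.40 - fail(0.03)
    lactate <- 1.0 + t_d * 0.2 + fail(1.2)
    glucose <- rep(5.5, length(t_d))
    jitter <- function(x, lo = -Inf) {
      pmax(lo, x * (1 + stats::rnorm(length(x), sd = noise_rel)))
    }
    df <- data.frame(
      time_h = t_h,
      flow_ml_min = jitter(flow, lo = 0),
      map_mmhg = jitter(rep(75, length(t_d)), lo = 0),
      po2_art = jitter(po2_art, lo = 0),
      po2_ven = jitter(po2_ven, lo = 0),
      ph = ph + stats::rnorm(length(t_d), sd = noise_rel),
      lactate_mmol_l = jitter(lactate, lo = 0),
      glucose_mmol_l = jitter(glucose, lo = 0)
    )
    w0 <- stats::rnorm(1, 283, 10)
    gain <- 0.28 * min(1, days / 8)
    attr(df, "weight_initial_g") <- w0
    attr(df, "weight_final_g") <- w0 * (1 + gain)
    class(df) <- c("perfusion_timeseries", "data.frame")
    df
  })
}
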