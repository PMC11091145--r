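# Relative TCA-cycle flux ratios from 13C5-glutamine fraction enrichments
# at pseudo-steady state.
#
# With a 13C5-glutamine tracer, glutaminase (GLS) produces glutamate m+5,
# which dilutes into the alpha-ketoglutarate pool alongside unlabeled carbon
# supplied through isocitrate dehydrogenase (IDH). One oxidative turn
# converts m+5 alpha-KG to m+4 succinate (OGDH) and onward to m+4 malate
# (SDH forward). At pseudo-steady state the enrichment ratios along this
# chain report the relative rates of the enzymes:
#
#   V_GLS/V_OGDH  = glutamate(m+5) / glutamine(m+5)
#   V_GLS/V_IDH   = r / (1 - r),  r = glutamate(m+5)/glutamine(m+5)
#   V_OGDH/V_SDHF = succinate(m+4) / glutamate(m+5)
#   V_SDHF/V_MDH  = malate(m+4) / succinate(m+4)
#
# Note the last ratio uses m+4 for both metabolites: succinate and malate
# have four carbons, so m+5 species cannot exist.

QFLUX_EPS <- 1e-6

qflux_invalid <- function(reason) {
  structure(NA_real_, invalid = TRUE, reason = reason)
}

qflux_check_fraction <- function(x, name) {
  if (is.null(x) || length(x) != 1L || is.na(x)) {
    return(qflux_invalid(sprintf("%s is masked", name)))
  }
  if (x < 0 || x > 1) stop_arg("%s must be a fraction in [0, 1]", name)
  NULL
}

#' Relative rate of glutaminase over alpha-KG dehydrogenase
#'
#' `glutamate(m+5) / glutamine(m+5)`: the fraction of the glutamate pool
#' made directly from labeled glutamine.
#'
#' @param glu_m5 glutamate M+5 fraction enrichment (corrected).
#' @param gln_m5 glutamine M+5 fraction enrichment (corrected).
#' @param eps denominator guard on fractions (default 1e-6).
#' @return positive ratio, or an NA flagged with attributes `invalid` and
#'   `reason` when the input is masked or degenerate.
#' @examples
#' v_gls_over_ogdh(0.4, 0.8)  # 0.5
#' @export
v_gls_over_ogdh <- function(glu_m5, gln_m5, eps = QFLUX_EPS) {
  for (chk in list(qflux_check_fraction(glu_m5, "glu_m5"),
                   qflux_check_fraction(gln_m5, "gln_m5"))) {
    if (!is.null(chk)) return(chk)
  }
  if (gln_m5 <= eps) return(qflux_invalid("zero denominator (gln_m5)"))
  if (glu_m5 <= eps) return(qflux_invalid("zero numerator (glu_m5)"))
  glu_m5 / gln_m5
}

#' Relative rate of glutaminase over isocitrate dehydrogenase
#'
#' With r the glutamine-derived fraction of the alpha-KG pool
#' (`glutamate(m+5)/glutamine(m+5)`), the IDH-derived fraction is 1 - r, so
#' the rate ratio is `r / (1 - r)`. Requires r strictly inside (0, 1).
#'
#' @inheritParams v_gls_over_ogdh
#' @return positive ratio or flagged NA.
#' @examples
#' v_gls_over_idh(0.4, 0.8)  # 1
#' @export
v_gls_over_idh <- function(glu_m5, gln_m5, eps = QFLUX_EPS) {
  r <- v_gls_over_ogdh(glu_m5, gln_m5, eps)
  if (isTRUE(attr(r, "invalid"))) return(r)
  if (r >= 1 - eps) return(qflux_invalid("glutamine-derived fraction at or above 1"))
  as.numeric(r) / (1 - as.numeric(r))
}

#' Relative rate of alpha-KG dehydrogenase over succinate dehydrogenase
#'
#' `succinate(m+4) / glutamate(m+5)`: the fraction of the succinate pool
#' derived from labeled alpha-KG/glutamate.
#'
#' @param succ_m4 succinate M+4 fraction enrichment (corrected).
#' @param glu_m5 glutamate M+5 fraction enrichment (corrected).
#' @inheritParams v_gls_over_ogdh
#' @return positive ratio or flagged NA.
#' @export
v_ogdh_over_sdhf <- function(succ_m4, glu_m5, eps = QFLUX_EPS) {
  for (chk in list(qflux_check_fraction(succ_m4, "succ_m4"),
                   qflux_check_fraction(glu_m5, "glu_m5"))) {
    if (!is.null(chk)) return(chk)
  }
  if (glu_m5 <= eps) return(qflux_invalid("zero denominator (glu_m5)"))
  if (succ_m4 <= eps) return(qflux_invalid("zero numerator (succ_m4)"))
  succ_m4 / glu_m5
}

#' Relative rate of succinate dehydrogenase (forward) over malate dehydrogenase
#'
#' `malate(m+4) / succinate(m+4)`: the fraction of the malate pool derived
#' directly from forward SDH flux. A zero numerator is flagged invalid
#' rather than reported as 0, since a zero forward flux contradicts the
#' steady-state model.
#'
#' @param mal_m4 malate M+4 fraction enrichment (corrected).
#' @param succ_m4 succinate M+4 fraction enrichment (corrected).
#' @inheritParams v_gls_over_ogdh
#' @return positive ratio or flagged NA.
#' @export
v_sdhf_over_mdh <- function(mal_m4, succ_m4, eps = QFLUX_EPS) {
  for (chk in list(qflux_check_fraction(mal_m4, "mal_m4"),
                   qflux_check_fraction(succ_m4, "succ_m4"))) {
    if (!is.null(chk)) return(chk)
  }
  if (succ_m4 <= eps) return(qflux_invalid("zero denominator (succ_m4)"))
  if (mal_m4 <= eps) return(qflux_invalid("zero numerator (mal_m4)"))
  mal_m4 / succ_m4
}

#' Compute the full set of relative TCA flux ratios
#'
#' Applies the four ratio definitions to one set of corrected cluster-level
#' enrichments and records the inputs and any invalidity reasons.
#'
#' @param enrichments named list or vector with entries `gln_m5`, `glu_m5`,
#'   `succ_m4`, `mal_m4` (corrected fraction enrichments; NA = masked).
#' @param eps denominator guard (default 1e-6).
#' @return object of class `flux_ratio_set`: list with the four ratios
#'   (`v_gls_over_ogdh`, `v_gls_over_idh`, `v_ogdh_over_sdhf`,
#'   `v_sdhf_over_mdh`), `inputs`, `eps`.
#' @examples
#' compute_flux_set(c(gln_m5 = 0.8, glu_m5 = 0.4, succ_m4 = 0.2, mal_m4 = 0.1))
#' @export
compute_flux_set <- function(enrichments, eps = QFLUX_EPS) {
  e <- as.list(enrichments)
  need <- c("gln_m5", "glu_m5", "succ_m4", "mal_m4")
  for (nm in need) if (is.null(e[[nm]])) e[[nm]] <- qflux_na_missing(nm)
  structure(
    list(
      v_gls_over_ogdh  = v_gls_over_ogdh(e$glu_m5, e$gln_m5, eps),
      v_gls_over_idh   = v_gls_over_idh(e$glu_m5, e$gln_m5, eps),
      v_ogdh_over_sdhf = v_ogdh_over_sdhf(e$succ_m4, e$glu_m5, eps),
      v_sdhf_over_mdh  = v_sdhf_over_mdh(e$mal_m4, e$succ_m4, eps),
      inputs = e[need],
      eps = eps
    ),
    class = "flux_ratio_set"
  )
}

qflux_na_missing <- function(nm) NA_real_

#' @export
print.flux_ratio_set <- function(x, ...) {
  cat("Relative TCA-cycle flux ratios (13C5-glutamine, pseudo-steady state)\n")
  nm <- c(v_gls_over_ogdh = "V_GLS/V_OGDH", v_gls_over_idh = "V_GLS/V_IDH",
          v_ogdh_over_sdhf = "V_OGDH/V_SDH(F)", v_sdhf_over_mdh = "V_SDH(F)/V_MDH")
  for (k in names(nm)) {
    v <- x[[k]]
    if (isTRUE(attr(v, "invalid")) || is.na(v)) {
      cat(sprintf("  %-16s invalid (%s)\n", nm[[k]],
                  attr(v, "reason") %||% "missing input"))
    } else {
      cat(sprintf("  %-16s %.4f\n", nm[[k]], v))
    }
  }
  invisible(x)
}

#' Is a flux ratio valid?
#'
#' @param x a single ratio returned by the `v_*` functions.
#' @return TRUE when the ratio is a finite positive number.
#' @export
is_valid_ratio <- function(x) {
  !is.na(x) && !isTRUE(attr(x, "invalid")) && is.finite(x) && x > 0
}
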