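# Natural-abundance / tracer-purity correction of 13C isotopologue
# distributions, and fraction enrichment.

#' Forward convolution model for 13C isotopologue distributions
#'
#' Column j of the forward matrix is the probability distribution of the
#' observed mass shift M+k for a molecule that truly carries j tracer-derived
#' carbons: each of the j nominally labeled carbons is truly 13C with
#' probability `tracer_purity` and otherwise behaves as a natural-abundance
#' carbon (13C with probability `p13c`), while each of the remaining n-j
#' carbons is 13C with the natural abundance `p13c`. The observed
#' distribution is therefore the convolution of Binomial(j, q) with
#' Binomial(n-j, p13c), where q = purity + (1-purity) * p13c. Every column
#' sums to 1.
#'
#' Folding tracer purity into the same matrix as natural abundance means a
#' single inversion performs both corrections.
#'
#' @param n_carbons number of carbon atoms in the metabolite skeleton.
#' @param p13c natural 13C abundance fraction, in `[0, 0.5)`; default 0.0107.
#' @param tracer_purity per-atom isotopic purity of the tracer, in `(0, 1]`;
#'   default 0.99.
#' @return object of class `correction_model` with fields `n_carbons`,
#'   `p13c`, `tracer_purity`, `forward` ((n+1) x (n+1) matrix).
#' @examples
#' m <- build_forward_matrix(2, p13c = 0.0107, tracer_purity = 1)
#' m$forward[, 1]  # unlabeled pool: (1-p)^2, 2p(1-p), p^2
#' @export
build_forward_matrix <- function(n_carbons, p13c = 0.0107,
                                 tracer_purity = 0.99) {
  if (!is.numeric(n_carbons) || n_carbons < 1 || n_carbons != round(n_carbons)) {
    stop_arg("n_carbons must be a positive integer")
  }
  if (!is.numeric(p13c) || p13c < 0 || p13c >= 0.5) {
    stop_arg("p13c must lie in [0, 0.5)")
  }
  if (!is.numeric(tracer_purity) || tracer_purity <= 0 || tracer_purity > 1) {
    stop_arg("tracer_purity must lie in (0, 1]")
  }
  n <- as.integer(n_carbons)
  q <- tracer_purity + (1 - tracer_purity) * p13c
  fwd <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    lab <- stats::dbinom(0:j, size = j, prob = q)
    nat <- stats::dbinom(0:(n - j), size = n - j, prob = p13c)
    # convolve the two binomials: observed k = labeled 13C + natural 13C
    col <- rep(0, n + 1L)
    for (a in 0:j) {
      ks <- a + 0:(n - j)
      col[ks + 1L] <- col[ks + 1L] + lab[a + 1L] * nat
    }
    fwd[, j + 1L] <- col
  }
  dimnames(fwd) <- list(paste0("obs_M", 0:n), paste0("true_M", 0:n))
  structure(list(n_carbons = n, p13c = p13c, tracer_purity = tracer_purity,
                 forward = fwd),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("correction_model: %d carbons, p13c = %.4g, tracer purity = %.4g\n",
              x$n_carbons, x$p13c, x$tracer_purity))
  invisible(x)
}

#' Apply the forward model to a true isotopologue distribution
#'
#' @param model a [build_forward_matrix()] result.
#' @param fractions length n+1 non-negative vector of true M+0..M+n fractions.
#' @return observed fraction vector of the same length.
#' @export
apply_forward <- function(model, fractions) {
  stopifnot(inherits(model, "correction_model"))
  if (length(fractions) != model$n_carbons + 1L) {
    stop_arg("fraction vector length must be n_carbons + 1")
  }
  as.numeric(model$forward %*% fractions)
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
# Small dense problems only (isotopologue vectors are at most ~7 long).
nnls_solve <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  x <- rep(0, n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol && iter < 30L * n) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- rep(0, n)
      z[passive] <- as.numeric(solve(crossprod(Ap), crossprod(Ap, b)))
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Correct an observed isotopologue distribution
#'
#' Deconvolves natural 13C abundance and tracer impurity from an observed
#' isotopologue intensity vector by solving `forward %*% x ~ observed` under
#' a non-negativity constraint, then renormalizing `x` to sum to 1. With
#' `method = "solve"` the unconstrained exact inverse is used instead
#' (useful for exactness checks on noiseless data; may go negative under
#' noise).
#'
#' @param observed numeric vector of observed M+0..M+n intensities (any
#'   scale) or an isotopologue group list with field `intensities`.
#' @param model a matching [build_forward_matrix()].
#' @param method `"nnls"` (default) or `"solve"`.
#' @return list with `fractions` (length n+1, sums to 1; all `NA` when the
#'   observation is all-zero — a masked value, not an error), `residual`
#'   (Euclidean norm of `forward %*% x - observed/sum(observed)`), `masked`.
#' @examples
#' m <- build_forward_matrix(2, 0.0107, 1)
#' obs <- apply_forward(m, c(0.2, 0, 0.8))
#' correct_distribution(obs, m)$fractions
#' @export
correct_distribution <- function(observed, model, method = c("nnls", "solve")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "correction_model"))
  if (is.list(observed)) observed <- observed$intensities
  if (length(observed) != model$n_carbons + 1L) {
    stop_arg("observed vector length must be n_carbons + 1")
  }
  if (any(observed < 0)) stop_arg("observed intensities must be non-negative")
  tot <- sum(observed)
  if (tot <= 0) {
    return(list(fractions = rep(NA_real_, length(observed)),
                residual = NA_real_, masked = TRUE))
  }
  b <- observed / tot
  x <- switch(method,
    nnls = nnls_solve(model$forward, b),
    solve = as.numeric(solve(model$forward, b))
  )
  s <- sum(x)
  fr <- if (s > 0) x / s else rep(NA_real_, length(x))
  list(fractions = fr,
       residual = sqrt(sum((model$forward %*% x - b)^2)),
       masked = all(is.na(fr)))
}

#' Isotopologue group
#'
#' Bundles a metabolite's M+0..M+n channel intensities with its carbon
#' count, the unit of isotope correction and enrichment.
#'
#' @param metabolite metabolite name.
#' @param n_carbons carbon count of the skeleton.
#' @param intensities non-negative numeric vector of length `n_carbons + 1`.
#' @return list of class `isotopologue_group`.
#' @export
isotopologue_group <- function(metabolite, n_carbons, intensities) {
  n_carbons <- as.integer(n_carbons)
  if (length(intensities) != n_carbons + 1L) {
    stop_arg("%s: need %d intensities (M+0..M+%d), got %d",
             metabolite, n_carbons + 1L, n_carbons, length(intensities))
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop_arg("%s: intensities must be finite and non-negative", metabolite)
  }
  structure(list(metabolite = metabolite, n_carbons = n_carbons,
                 intensities = as.numeric(intensities)),
            class = "isotopologue_group")
}

#' Fraction enrichment of an isotopologue group
#'
#' The fraction of a metabolite's pool in each isotopologue: element k is
#' intensity(M+k) divided by the summed intensity over M+0..M+n. Scale
#' invariant by construction. An all-zero group yields a masked (all-NA)
#' vector rather than an error.
#'
#' @param group an [isotopologue_group()] or plain non-negative vector.
#' @return numeric vector of fractions summing to 1, or all-NA when masked.
#' @examples
#' fraction_enrichment(c(5, 3, 2))
#' @export
fraction_enrichment <- function(group) {
  x <- if (inherits(group, "isotopologue_group")) group$intensities else group
  if (any(x < 0, na.rm = TRUE)) stop_arg("intensities must be non-negative")
  tot <- sum(x)
  if (!is.finite(tot) || tot <= 0) return(rep(NA_real_, length(x)))
  x / tot
}

#' Fraction of carbon atoms labeled
#'
#' Atom-level label content of a pool: sum over k of k times the M+k
#' fraction, divided by the carbon count. Ranges from 0 (unlabeled) to 1
#' (uniformly labeled).
#'
#' @param group an [isotopologue_group()], or a fraction vector (then
#'   `n_carbons` is inferred as its length minus 1).
#' @param fractions optional pre-corrected fraction vector; defaults to
#'   [fraction_enrichment()] of the group.
#' @return scalar fraction in `[0, 1]`, NA if the input is masked.
#' @export
carbon_contribution <- function(group, fractions = NULL) {
  if (inherits(group, "isotopologue_group")) {
    n <- group$n_carbons
    if (is.null(fractions)) fractions <- fraction_enrichment(group)
  } else {
    fractions <- if (is.null(fractions)) fraction_enrichment(group) else fractions
    n <- length(fractions) - 1L
  }
  if (anyNA(fractions)) return(NA_real_)
  sum((seq_along(fractions) - 1L) * fractions) / n
}
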