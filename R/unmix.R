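#' Unmix a titration spectrum into dissociation degrees
#'
#' Fits a mixture spectrum as a least-squares linear combination of the
#' four pure-species spectra,
#' \deqn{A(\lambda) = c_{HA} s_{HA}(\lambda) + c_{A} s_{A}(\lambda) +
#'       c_{HB} s_{HB}(\lambda) + c_{B} s_{B}(\lambda),}
#' and converts the fitted coefficients into the dissociation degrees
#' \eqn{\alpha_{HA} = c_A / (c_{HA} + c_A)} and
#' \eqn{\alpha_{HB} = c_B / (c_{HB} + c_B)}.  Because only the ratio of
#' coefficients enters \eqn{\alpha}, dilution of the cuvette contents by
#' titrant addition cancels out.  Negative fitted coefficients (possible
#' with noisy spectra) are clipped to zero before forming \eqn{\alpha};
#' the raw coefficients are retained for diagnostics.
#'
#' @param mixture A [uv_spectrum] on the same wavelength grid as
#'   `basis`.
#' @param basis A [species_basis].
#' @param window Numeric length-2: the range of dissociation degrees
#'   considered accurately measurable (applied to both acids at once).
#' @param condition_threshold Maximum accepted condition number of the
#'   basis matrix; beyond it the fit is refused and the most nearly
#'   collinear pair of basis spectra is named.
#' @return An object of class `dissociation_state` with elements
#'   `alpha_ha`, `alpha_hb`, `in_window`, `residual_norm`,
#'   `coefficients` (clipped) and `raw_coefficients`.
#' @export
unmix <- function(mixture, basis, window = c(0.1, 0.9),
                  condition_threshold = 1e8) {
  if (!is_uv_spectrum(mixture)) stop("mixture must be a uv_spectrum",
                                     call. = FALSE)
  if (!inherits(basis, "species_basis"))
    stop("basis must be a species_basis", call. = FALSE)
  if (!same_grid(mixture, basis$s_ha))
    stop("mixture must be on the basis wavelength grid", call. = FALSE)
  B <- basis_matrix(basis)
  kap <- kappa(B, exact = TRUE)
  if (!is.finite(kap) || kap > condition_threshold) {
    # name the most nearly collinear pair of columns
    cn <- colnames(B)
    worst <- c(NA_character_, NA_character_); wcos <- -1
    for (i in 1:3) for (j in (i + 1):4) {
      ci <- B[, i]; cj <- B[, j]
      cosij <- abs(sum(ci * cj)) /
        max(sqrt(sum(ci^2)) * sqrt(sum(cj^2)), .Machine$double.xmin)
      if (cosij > wcos) { wcos <- cosij; worst <- cn[c(i, j)] }
    }
    stop(sprintf(
      "basis matrix is ill-conditioned (condition number %.3g > %.3g); near-collinear pair: %s and %s",
      kap, condition_threshold, worst[1], worst[2]), call. = FALSE)
  }
  fit <- stats::lm.fit(B, mixture$absorbance)
  raw <- fit$coefficients
  residual_norm <- sqrt(sum(fit$residuals^2))
  cc <- pmax(raw, 0)
  tot_a <- cc["HA"] + cc["A"]
  tot_b <- cc["HB"] + cc["B"]
  eps <- 1e-10 * max(sum(cc), 1)
  if (tot_a <= eps)
    stop("degenerate fit: total concentration coefficient of the first acid (c_HA + c_A) is ~0",
         call. = FALSE)
  if (tot_b <= eps)
    stop("degenerate fit: total concentration coefficient of the second acid (c_HB + c_B) is ~0",
         call. = FALSE)
  dissociation_state(alpha_ha = unname(cc["A"] / tot_a),
                     alpha_hb = unname(cc["B"] / tot_b),
                     window = window,
                     residual_norm = residual_norm,
                     coefficients = cc,
                     raw_coefficients = raw)
}

#' Dissociation state of an acid pair in one titration mixture
#'
#' @param alpha_ha,alpha_hb Dissociation degrees in `[0, 1]`.
#' @param window Measurable-alpha window applied to both acids.
#' @param residual_norm Unitless least-squares residual norm of the
#'   spectral fit (0 for states constructed directly).
#' @param coefficients,raw_coefficients Optional fitted species
#'   coefficients (clipped / as fitted).
#' @return An object of class `dissociation_state`.
#' @export
dissociation_state <- function(alpha_ha, alpha_hb, window = c(0.1, 0.9),
                               residual_norm = 0, coefficients = NULL,
                               raw_coefficients = NULL) {
  stopifnot(is.numeric(alpha_ha), is.numeric(alpha_hb),
            length(alpha_ha) == 1L, length(alpha_hb) == 1L)
  if (alpha_ha < 0 || alpha_ha > 1 || alpha_hb < 0 || alpha_hb > 1)
    stop("dissociation degrees must lie in [0, 1]", call. = FALSE)
  window <- sort(as.numeric(window))
  structure(list(
    alpha_ha = alpha_ha, alpha_hb = alpha_hb,
    in_window = alpha_ha >= window[1] && alpha_ha <= window[2] &&
      alpha_hb >= window[1] && alpha_hb <= window[2],
    residual_norm = residual_norm,
    coefficients = coefficients, raw_coefficients = raw_coefficients,
    window = window), class = "dissociation_state")
}

#' @export
print.dissociation_state <- function(x, ...) {
  cat(sprintf(
    "<dissociation_state> alpha_HA = %.4f, alpha_HB = %.4f (%s window), residual = %.3g\n",
    x$alpha_ha, x$alpha_hb, if (x$in_window) "in" else "outside",
    x$residual_norm))
  invisible(x)
}

#' Per-mixture relative acidity from dissociation degrees
#'
#' The equilibrium \eqn{HA + B^- \rightleftharpoons A^- + HB} gives, at
#' every titration point,
#' \deqn{\Delta pK_a = pK_a(HB) - pK_a(HA) =
#'   \log_{10}\frac{\alpha_{HA}(1-\alpha_{HB})}
#'                 {(1-\alpha_{HA})\,\alpha_{HB}}.}
#' The sign convention is fixed so that a positive value means the
#' second acid HB is the weaker one.  Swapping the two acids negates the
#' value exactly.
#'
#' @param state A `dissociation_state`, or the numeric
#'   \eqn{\alpha_{HA}}.
#' @param alpha_hb \eqn{\alpha_{HB}} when `state` is numeric.
#' @return The per-point \eqn{\Delta pK_a} (pKa units); `NA` with a
#'   warning when either degree sits at 0 or 1, where the value is
#'   undefined.
#' @examples
#' delta_pka_point(0.9, 0.1)  # log10(81)
#' @export
delta_pka_point <- function(state, alpha_hb = NULL) {
  if (inherits(state, "dissociation_state")) {
    a <- state$alpha_ha; b <- state$alpha_hb
  } else {
    a <- as.numeric(state); b <- as.numeric(alpha_hb)
  }
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (a <= 0 || a >= 1 || b <= 0 || b >= 1) {
    warning("delta pKa undefined at alpha of 0 or 1; point excluded",
            call. = FALSE)
    return(NA_real_)
  }
  log10(a * (1 - b) / ((1 - a) * b))
}

#' Aggregate per-mixture values into a delta-pKa series
#'
#' One measurement series titrates one acid pair through many mixtures;
#' each mixture with both dissociation degrees inside the measurable
#' window contributes one per-point value.  The series value is the
#' unweighted mean of those points.  Series whose magnitude exceeds
#' `reliability_threshold` are flagged low-reliability: beyond roughly
#' 1.5 pKa units there is little or no region where both acids are
#' partially dissociated at once, and such determinations need
#' confirmation.
#'
#' @param states List of `dissociation_state` objects (one per recorded
#'   mixture).
#' @param acid_1,acid_2 Identifiers of the two acids; the aggregate is
#'   `pKa(acid_2) - pKa(acid_1)`.
#' @param window Measurable-alpha window; only points with both degrees
#'   inside it are used.
#' @param reliability_threshold Magnitude above which the series is
#'   flagged `"low"`.
#' @return An object of class `delta_pka_series` with the per-point
#'   values, the aggregate, its within-series standard deviation,
#'   `n_valid` and a reliability flag.
#' @export
aggregate_series <- function(states, acid_1, acid_2, window = c(0.1, 0.9),
                             reliability_threshold = 1.5) {
  if (inherits(states, "dissociation_state")) states <- list(states)
  if (!length(states) ||
      !all(vapply(states, inherits, logical(1), "dissociation_state")))
    stop("states must be a non-empty list of dissociation_state objects",
         call. = FALSE)
  window <- sort(as.numeric(window))
  a <- vapply(states, `[[`, numeric(1), "alpha_ha")
  b <- vapply(states, `[[`, numeric(1), "alpha_hb")
  pts <- suppressWarnings(
    vapply(seq_along(states), function(i) delta_pka_point(a[i], b[i]),
           numeric(1)))
  valid <- is.finite(pts) &
    a >= window[1] & a <= window[2] & b >= window[1] & b <= window[2]
  if (!any(valid))
    stop("no measurable overlap window: no mixture has both dissociation degrees inside [",
         window[1], ", ", window[2], "]", call. = FALSE)
  agg <- mean(pts[valid])
  structure(list(
    acid_1 = acid_1, acid_2 = acid_2,
    point_values = pts, valid = valid,
    aggregate = agg,
    within_series_sd = if (sum(valid) > 1) stats::sd(pts[valid]) else NA_real_,
    n_valid = sum(valid),
    reliability_flag = if (abs(agg) > reliability_threshold) "low" else "high"),
    class = "delta_pka_series")
}

#' @export
print.delta_pka_series <- function(x, ...) {
  cat(sprintf(
    "<delta_pka_series> %s -> %s: delta pKa = %.4f (sd %.4f, n = %d, %s reliability)\n",
    x$acid_1, x$acid_2, x$aggregate,
    if (is.na(x$within_series_sd)) 0 else x$within_series_sd,
    x$n_valid, x$reliability_flag))
  invisible(x)
}
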