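#' Describe a synthetic acid for titration simulation
#'
#' A synthetic acid has a known true pKa and Gaussian-band UV-vis
#' spectra for its neutral and anionic forms, mimicking the smooth
#' absorption bands of conjugated NH acids.
#'
#' @param name Identifier.
#' @param true_pka Ground-truth pKa in the simulated solvent.
#' @param neutral_bands,anion_bands Data frames (or matrices) with
#'   columns `center` (nm), `width` (nm, > 0) and `height`
#'   (AU per unit concentration, >= 0); one row per Gaussian band.
#' @param concentration Formal concentration in mol/L (> 0).
#' @return An object of class `acid_spec`.
#' @export
acid_spec <- function(name, true_pka, neutral_bands, anion_bands,
                      concentration = 1e-4) {
  chk <- function(b, what) {
    b <- as.data.frame(b)
    if (nrow(b)) {
      if (!all(c("center", "width", "height") %in% names(b)))
        stop(what, " bands need columns center, width, height",
             call. = FALSE)
      if (any(b$width <= 0) || any(b$height < 0))
        stop(what, " bands need width > 0 and height >= 0", call. = FALSE)
    }
    b
  }
  if (!is.finite(concentration) || concentration <= 0)
    stop("concentration must be > 0", call. = FALSE)
  structure(list(name = as.character(name), true_pka = true_pka,
                 neutral_bands = chk(neutral_bands, "neutral"),
                 anion_bands = chk(anion_bands, "anion"),
                 concentration = concentration), class = "acid_spec")
}

#' Generate a Gaussian-band spectrum for one form of an acid
#'
#' @param spec An [acid_spec].
#' @param form `"neutral"` or `"anion"`.
#' @param grid Wavelength grid (nm).
#' @param concentration Formal concentration the spectrum is scaled to;
#'   defaults to the spec's own.  Use `1` for a unit-concentration
#'   basis spectrum.
#' @return A [uv_spectrum]: the pointwise sum of the form's Gaussian
#'   bands, scaled by `concentration`.
#' @export
gen_spectrum <- function(spec, form = c("neutral", "anion"),
                         grid = seq(220, 500, by = 1),
                         concentration = spec$concentration) {
  stopifnot(inherits(spec, "acid_spec"))
  form <- match.arg(form)
  bands <- if (form == "neutral") spec$neutral_bands else spec$anion_bands
  a <- numeric(length(grid))
  for (i in seq_len(nrow(bands)))
    a <- a + bands$height[i] *
      exp(-0.5 * ((grid - bands$center[i]) / bands$width[i])^2)
  uv_spectrum(grid, a * concentration)
}

#' Plan a two-acid titration with a strong base
#'
#' @param acid_a,acid_b [acid_spec] objects for the two acids HA and
#'   HB.
#' @param base_additions Nondecreasing vector of total added strong
#'   base (mol/L); maximum must not exceed the total acid
#'   concentration.
#' @param noise_sd Relative (multiplicative) Gaussian noise on
#'   absorbance; 0 for noiseless spectra.
#' @param seed Integer seed fixing the noise realization.
#' @param grid Wavelength grid for the generated spectra.
#' @return An object of class `titration_plan`.
#' @export
titration_plan <- function(acid_a, acid_b, base_additions, noise_sd = 0,
                           seed = 1L, grid = seq(220, 500, by = 1)) {
  stopifnot(inherits(acid_a, "acid_spec"), inherits(acid_b, "acid_spec"))
  base_additions <- as.numeric(base_additions)
  if (any(diff(base_additions) < 0))
    stop("base_additions must be nondecreasing", call. = FALSE)
  tot <- acid_a$concentration + acid_b$concentration
  if (any(base_additions < 0) || max(base_additions) > tot + 1e-15)
    stop("base additions must lie in [0, total acid concentration]",
         call. = FALSE)
  structure(list(acid_a = acid_a, acid_b = acid_b,
                 base_additions = base_additions,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 grid = grid), class = "titration_plan")
}

# speciation of HA/HB competing for D mol/L of fully consumed strong
# base: conservation cA*aA + cB*aB = D and mass action
# aA(1-aB)/((1-aA)aB) = 10^(pKa_B - pKa_A)
solve_speciation <- function(c_a, c_b, delta_pka, D, tol = 1e-12) {
  if (D <= 0) return(c(alpha_ha = 0, alpha_hb = 0))
  K <- 10^delta_pka
  alpha_b_of <- function(aa) aa / (aa + K * (1 - aa))
  f <- function(aa) c_a * aa + c_b * alpha_b_of(aa) - D
  if (D >= c_a + c_b) return(c(alpha_ha = 1, alpha_hb = 1))
  root <- stats::uniroot(f, c(0, 1), tol = tol)$root
  # Newton polish to push the conservation residual to machine level
  for (i in 1:3) {
    aa <- root
    ab <- alpha_b_of(aa)
    dab <- K / (aa + K * (1 - aa))^2
    fr <- c_a * aa + c_b * ab - D
    root <- min(max(aa - fr / (c_a + c_b * dab), 0), 1)
  }
  c(alpha_ha = root, alpha_hb = alpha_b_of(root))
}

#' Simulate a two-acid spectrophotometric titration
#'
#' Emulates the relative-acidity measurement: two weak acids in one
#' cuvette are titrated stepwise with a strong base.  The titrant is
#' treated as infinitely strong relative to the acids (every added
#' equivalent is fully consumed by deprotonation), so at total base
#' addition D the speciation obeys the conservation
#' `c_A * alpha_HA + c_B * alpha_HB = D` together with the mass-action
#' relation fixed by the true \eqn{\Delta pK_a}; the one-dimensional
#' monotone root is located to tolerance 1e-12 and polished to machine
#' level.  Each mixture spectrum is the linear combination of the four
#' pure-species spectra with optional multiplicative Gaussian noise.
#'
#' @param plan A [titration_plan].
#' @return A list of class `titration_sim`: `basis` (the
#'   unit-concentration [species_basis]), `mixtures` (list of
#'   [uv_spectrum]), `speciation` (data frame `D`, `alpha_ha`,
#'   `alpha_hb`), `true_delta_pka` and `plan`.
#' @export
gen_titration <- function(plan) {
  stopifnot(inherits(plan, "titration_plan"))
  a <- plan$acid_a; b <- plan$acid_b
  grid <- plan$grid
  basis <- species_basis(
    gen_spectrum(a, "neutral", grid, concentration = 1),
    gen_spectrum(a, "anion", grid, concentration = 1),
    gen_spectrum(b, "neutral", grid, concentration = 1),
    gen_spectrum(b, "anion", grid, concentration = 1))
  true_delta <- b$true_pka - a$true_pka
  set.seed(plan$seed)
  spec <- t(vapply(plan$base_additions, function(D)
    solve_speciation(a$concentration, b$concentration, true_delta, D),
    numeric(2)))
  B <- basis_matrix(basis)
  mixtures <- lapply(seq_along(plan$base_additions), function(i) {
    aa <- spec[i, 1]; ab <- spec[i, 2]
    conc <- c(a$concentration * (1 - aa), a$concentration * aa,
              b$concentration * (1 - ab), b$concentration * ab)
    y <- as.numeric(B %*% conc)
    if (plan$noise_sd > 0)
      y <- y * (1 + stats::rnorm(length(y), 0, plan$noise_sd))
    uv_spectrum(grid, y)
  })
  structure(list(basis = basis, mixtures = mixtures,
                 speciation = data.frame(D = plan$base_additions,
                                         alpha_ha = spec[, 1],
                                         alpha_hb = spec[, 2]),
                 true_delta_pka = true_delta, plan = plan),
            class = "titration_sim")
}

#' Recover the relative acidity of a simulated titration
#'
#' Convenience wrapper running the full unmix-and-aggregate pipeline on
#' a simulated titration, as an end-to-end round trip against the known
#' ground truth.
#'
#' @param sim A `titration_sim` from [gen_titration()].
#' @param window Measurable-alpha window passed through to
#'   [aggregate_series()].
#' @return A `delta_pka_series`.
#' @export
unmix_titration <- function(sim, window = c(0.1, 0.9)) {
  stopifnot(inherits(sim, "titration_sim"))
  states <- lapply(sim$mixtures, unmix, basis = sim$basis, window = window)
  aggregate_series(states, sim$plan$acid_a$name, sim$plan$acid_b$name,
                   window = window)
}

#' Plan a synthetic relative-acidity measurement network
#'
#' The defaults mirror the scale of a realistic weak-acid study: around
#' forty acids spanning several pKa units, roughly 140 pairwise
#' measurements, a small set of anchor acids with known values, and a
#' measurement noise of 0.03 pKa units (the consistency a careful
#' spectrophotometric ladder achieves).
#'
#' @param n_acids Number of acids (nodes).
#' @param pka_range Range the true pKa values are drawn from
#'   (uniformly).
#' @param tiers Named fractions over `anchor`, `backbone`,
#'   `secondary`, `tertiary` (need not sum exactly to 1; backbone
#'   absorbs rounding).  At least one anchor is always assigned.
#' @param n_edges Number of measurement edges; defaults to
#'   `round(edge_density * n_acids * (n_acids - 1) / 2)` when
#'   `edge_density` is given, else ~3.4 edges per acid.
#' @param edge_density Fraction of all node pairs measured
#'   (alternative to `n_edges`).
#' @param noise_sd Gaussian noise on the measured edge
#'   \eqn{\Delta pK_a} values, pKa units.
#' @param seed Integer seed.
#' @return An object of class `network_plan`.
#' @export
network_plan <- function(n_acids = 42, pka_range = c(28, 34),
                         tiers = c(anchor = 0.12, backbone = 0.55,
                                   secondary = 0.28, tertiary = 0.05),
                         n_edges = NULL, edge_density = NULL,
                         noise_sd = 0.03, seed = 1L) {
  if (n_acids < 1L) stop("n_acids must be >= 1", call. = FALSE)
  tiers <- tiers[c("anchor", "backbone", "secondary", "tertiary")]
  tiers[is.na(tiers)] <- 0
  names(tiers) <- c("anchor", "backbone", "secondary", "tertiary")
  if (is.null(n_edges))
    n_edges <- if (!is.null(edge_density))
      round(edge_density * n_acids * (n_acids - 1) / 2)
    else round(3.4 * n_acids)
  structure(list(n_acids = as.integer(n_acids), pka_range = pka_range,
                 tiers = tiers, n_edges = as.integer(n_edges),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "network_plan")
}

#' Generate a measurement network with known true pKa values
#'
#' Draws true pKa values uniformly over the planned range, assigns
#' tiers, and builds a random measurement graph that is guaranteed to
#' be solvable tier by tier: every backbone acid is connected (through
#' backbone/anchor measurements) to an anchor, and every secondary or
#' tertiary acid has at least one measurement against an
#' earlier-assigned acid.  Each measured \eqn{\Delta pK_a} is the true
#' difference plus Gaussian noise.  Edge reliability classes follow the
#' tier of the step the edge is used in (`high` for backbone,
#' `medium` for secondary, `low` for tertiary).
#'
#' @param plan A [network_plan].
#' @return List with `graph` (a [measurement_graph]) and `true_pka`
#'   (named vector).
#' @export
gen_network <- function(plan) {
  stopifnot(inherits(plan, "network_plan"))
  set.seed(plan$seed)
  n <- plan$n_acids
  ids <- sprintf("acid%03d", seq_len(n))
  true <- stats::runif(n, plan$pka_range[1], plan$pka_range[2])
  names(true) <- ids
  # tier counts: at least one anchor; backbone absorbs rounding
  n_anchor <- max(1L, round(plan$tiers["anchor"] * n))
  n_tert <- round(plan$tiers["tertiary"] * n)
  n_sec <- round(plan$tiers["secondary"] * n)
  if (n_anchor + n_sec + n_tert > n) { n_sec <- 0L; n_tert <- 0L }
  n_back <- n - n_anchor - n_sec - n_tert
  tier <- rep(c("anchor", "backbone", "secondary", "tertiary"),
              c(n_anchor, n_back, n_sec, n_tert))
  tier <- sample(tier)  # random assignment of tiers to nodes
  # guarantee at least one anchor regardless of sampling
  lev <- tier_level(tier)
  # spanning connections: each non-anchor node links to a random node of
  # a lower-or-equal tier that is already reachable
  e1 <- character(0); e2 <- character(0)
  placed <- ids[tier == "anchor"]
  for (t in 1:3) {
    pool_prev <- placed
    members <- ids[lev == t]
    if (!length(members)) next
    members <- sample(members)
    for (m in members) {
      # partner restricted to already-placed nodes to keep each step anchored
      partner <- if (length(pool_prev) == 1L) pool_prev
                 else sample(pool_prev, 1)
      e1 <- c(e1, partner); e2 <- c(e2, m)
      pool_prev <- c(pool_prev, m)
    }
    placed <- pool_prev
  }
  # extra random measurements up to the planned count (duplicates allowed:
  # repeated series between one pair are separate measurements)
  n_extra <- max(0L, plan$n_edges - length(e1))
  if (n_extra > 0 && n > 1) {
    for (k in seq_len(n_extra)) {
      i <- sample.int(n, 1)
      rest <- setdiff(seq_len(n), i)
      j <- rest[sample.int(length(rest), 1)]
      e1 <- c(e1, ids[i]); e2 <- c(e2, ids[j])
    }
  }
  step_of_edge <- pmax(lev[match(e1, ids)], lev[match(e2, ids)])
  reliability <- c("high", "high", "medium", "low")[step_of_edge + 1L]
  delta <- true[e2] - true[e1] +
    if (plan$noise_sd > 0) stats::rnorm(length(e1), 0, plan$noise_sd) else 0
  nodes <- data.frame(id = ids, name = ids, tier = tier,
                      fixed_pka = ifelse(tier == "anchor", true, NA_real_))
  edges <- data.frame(acid_1 = e1, acid_2 = e2,
                      delta_pka = as.numeric(delta),
                      reliability = reliability,
                      included = rep(TRUE, length(e1)),
                      reason = rep(NA_character_, length(e1)))
  list(graph = measurement_graph(nodes, edges), true_pka = true)
}
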