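#' Physical constants used in gas-phase acidity assembly
#'
#' One place for the unit conversions: Hartree to kJ/mol, kcal to kJ,
#' and the Gibbs energy of the free proton used in the deprotonation
#' Gibbs energy.
#'
#' @return Named list: `hartree_to_kj` (2625.4996), `kcal_to_kj`
#'   (4.184), `g_proton_kcal` (-6.275) and the derived `g_proton_kj`.
#' @export
ga_constants <- function() {
  list(hartree_to_kj = 2625.4996,
       kcal_to_kj = 4.184,
       g_proton_kcal = -6.275,
       g_proton_kj = -6.275 * 4.184)
}

#' Complete-basis-set extrapolation of electronic energies
#'
#' Estimates the complete-basis-set (CBS) limit of a correlation
#' energy from calculations in correlation-consistent basis sets of
#' cardinal number X (2 = cc-pVDZ, 3 = cc-pVTZ, 4 = cc-pVQZ).  With
#' three cardinals the CBS value is the intercept of the least-squares
#' line of energy against \eqn{X^{-3}}; with exactly two it is solved
#' from the two-parameter expression \eqn{E(X) = E_{CBS} + A X^{-4}}.
#'
#' @param energies Named numeric vector of electronic energies in
#'   Hartree; names are the basis cardinals (subset of `2`, `3`, `4`,
#'   at least two present).
#' @return The extrapolated CBS energy (Hartree).
#' @examples
#' cbs_extrapolate(c(`2` = -100 + 5 / 8, `3` = -100 + 5 / 27,
#'                   `4` = -100 + 5 / 64))  # -100
#' @export
cbs_extrapolate <- function(energies) {
  energies <- unlist(energies)
  if (is.null(names(energies)) || any(!names(energies) %in% c("2", "3", "4")))
    stop("energies must be named by basis cardinal (2, 3, 4)",
         call. = FALSE)
  if (anyDuplicated(names(energies)))
    stop("duplicate basis cardinals", call. = FALSE)
  if (length(energies) < 2L)
    stop("at least two basis cardinals are required", call. = FALSE)
  x <- as.numeric(names(energies))
  e <- as.numeric(energies)
  if (length(e) >= 3L) {
    fit <- stats::lm(e ~ I(x^-3))
    unname(stats::coef(fit)[1])
  } else {
    # two-parameter form with integer exponent 4
    a <- (e[1] - e[2]) / (x[1]^-4 - x[2]^-4)
    e[1] - a * x[1]^-4
  }
}

#' Per-species thermochemical record
#'
#' @param species Species identifier (shared between an acid and its
#'   anion).
#' @param charge_state `"neutral"` (the acid HA) or `"anion"` (A-).
#' @param e_cbs CBS-extrapolated electronic energy, Hartree.
#' @param cp Chemical potential H - TS from the harmonic thermochemistry
#'   calculation, Hartree.
#' @return An object of class `species_thermo`.
#' @export
species_thermo <- function(species, charge_state = c("neutral", "anion"),
                           e_cbs, cp) {
  charge_state <- match.arg(charge_state)
  if (!is.finite(e_cbs) || !is.finite(cp))
    stop("e_cbs and cp must be finite", call. = FALSE)
  structure(list(species = as.character(species),
                 charge_state = charge_state,
                 e_cbs = e_cbs, cp = cp), class = "species_thermo")
}

#' Assemble a gas-phase acidity from acid and anion thermochemistry
#'
#' The gas-phase acidity is the Gibbs energy of the deprotonation
#' \eqn{HA(g) \rightarrow A^-(g) + H^+(g)}:
#' \deqn{GA = \left[(E_{CBS} + CP)_{A^-} - (E_{CBS} + CP)_{HA}\right]
#'   \cdot 2625.4996\ \mathrm{kJ\,mol^{-1}\,Hartree^{-1}} + G(H^+),}
#' with \eqn{G(H^+) = -6.275} kcal/mol (= -26.2546 kJ/mol).
#'
#' @param acid,anion [species_thermo] records for the neutral acid and
#'   its anion; `species` ids must match and charge states must be
#'   `"neutral"` / `"anion"` respectively.
#' @param constants Constant set, see [ga_constants()].
#' @return GA in kJ/mol.
#' @export
assemble_ga <- function(acid, anion, constants = ga_constants()) {
  stopifnot(inherits(acid, "species_thermo"),
            inherits(anion, "species_thermo"))
  if (acid$species != anion$species)
    stop(sprintf("mismatched species pair: %s vs %s", acid$species,
                 anion$species), call. = FALSE)
  if (acid$charge_state != "neutral" || anion$charge_state != "anion")
    stop("assemble_ga expects (neutral acid, anion) in that order",
         call. = FALSE)
  dG <- (anion$e_cbs + anion$cp) - (acid$e_cbs + acid$cp)
  dG * constants$hartree_to_kj +
    constants$g_proton_kcal * constants$kcal_to_kj
}

# "1431; 1440" -> c(1431, 1440); "" / NA -> numeric(0)
parse_ga_exp <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(numeric(0))
  as.numeric(trimws(strsplit(as.character(x), ";")[[1]]))
}

#' Compare experimental and computational gas-phase acidities
#'
#' Builds one (experimental, computational) pair per available
#' experimental GA value -- a compound with two literature values
#' contributes two pairs -- and summarizes the agreement by the
#' root-mean-square difference, the maximum absolute difference and the
#' mean bias (computational minus experimental).
#'
#' @param records Data frame with columns `ga_calc` (kJ/mol) and
#'   `ga_exp` (kJ/mol; multiple values per compound separated by `;`),
#'   plus optionally `name`.
#' @return An object of class `ga_comparison`: `pairs` data frame and
#'   unrounded `rms_diff`, `max_abs_diff`, `mean_bias`.  Printing
#'   rounds to whole kJ/mol, the resolution the input values support.
#' @export
compare_ga <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!all(c("ga_exp", "ga_calc") %in% names(records)))
    stop("records need columns ga_exp and ga_calc", call. = FALSE)
  nm <- if ("name" %in% names(records)) records$name
        else as.character(seq_len(nrow(records)))
  pairs <- list()
  for (i in seq_len(nrow(records))) {
    ev <- parse_ga_exp(records$ga_exp[i])
    if (!length(ev)) next
    cv <- as.numeric(records$ga_calc[i])
    if (!is.finite(cv))
      stop("compound with experimental GA lacks a computational value: ",
           nm[i], call. = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(
      compound = nm[i], ga_exp = ev, ga_calc = cv, diff = cv - ev)
  }
  if (!length(pairs))
    stop("no experimental GA values present", call. = FALSE)
  pairs <- do.call(rbind, pairs)
  structure(list(
    pairs = pairs,
    rms_diff = sqrt(mean(pairs$diff^2)),
    max_abs_diff = max(abs(pairs$diff)),
    mean_bias = mean(pairs$diff)), class = "ga_comparison")
}

#' @export
print.ga_comparison <- function(x, ...) {
  cat(sprintf(
    "<ga_comparison> %d exp/calc pairs: rms = %d, max |diff| = %d, mean bias = %d kJ/mol\n",
    nrow(x$pairs), round(x$rms_diff), round(x$max_abs_diff),
    round(x$mean_bias)))
  invisible(x)
}
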