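#' Default analysis configuration
#'
#' Central configuration for the pipeline.  All report rounding is
#' driven from here so internal math is never pre-rounded.
#'
#' @return A list of class `run_config`:
#' * `window` -- measurable dissociation-degree window (default
#'   `c(0.1, 0.9)`).
#' * `reliability_threshold` -- |delta pKa| above which a measurement
#'   is flagged low-reliability (default 1.5).
#' * `condition_threshold` -- basis-matrix conditioning limit for
#'   spectral unmixing (default 1e8).
#' * `rounding` -- decimals for reported values: conversion
#'   predictions (2), recommended values (1), assigned pKa (2; 1 for
#'   tertiary-tier acids), RMSE (2).
#' * `correlation_exclude` -- compounds left out of the
#'   solvent-correlation fit (default benzotriazole, whose acidity is
#'   ~5 orders of magnitude away from the rest of the set).
#' * `constants` -- unit constants, see [ga_constants()].
#' * `water_conversion` -- `FALSE`: water-to-MeCN conversion is
#'   shipped disabled; for weak acids of this type its prediction RMSE
#'   is well over 2 pKa units.
#' @export
default_config <- function() {
  structure(list(
    window = c(0.1, 0.9),
    reliability_threshold = 1.5,
    condition_threshold = 1e8,
    rounding = list(prediction = 2L, recommended = 1L, ladder = 2L,
                    ladder_tertiary = 1L, rmse = 2L),
    correlation_exclude = "1H-Benzotriazole",
    constants = ga_constants(),
    water_conversion = FALSE,
    seed = 1L), class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' Configurations round-trip losslessly (`load_config(save_config(x))`
#' is identical to `x`).
#'
#' @param config A `run_config` list.
#' @param path File path.
#' @return `load_config` returns the `run_config`; `save_config`
#'   returns `path` invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$rounding <- lapply(cfg$rounding, as.integer)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Read and write wide spectra CSV files
#'
#' The spectra interchange format is a wide CSV: first column
#' `wavelength_nm`, every further column one spectrum (UTF-8, decimal
#' point, header row mandatory).
#'
#' @param path CSV file path.
#' @param spectra Named list of [uv_spectrum] objects on a common grid.
#' @return `read_spectra_csv` returns a named list of [uv_spectrum];
#'   `write_spectra_csv` returns `path` invisibly.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("spectra file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE)
  if (names(d)[1] != "wavelength_nm")
    stop("first column must be wavelength_nm (found: ", names(d)[1], ")",
         call. = FALSE)
  if (ncol(d) < 2L) stop("no spectrum columns found", call. = FALSE)
  for (j in seq_along(d)) {
    v <- suppressWarnings(as.numeric(d[[j]]))
    if (any(is.na(v)))
      stop(sprintf("malformed numeric value in column '%s' at row %d",
                   names(d)[j], which(is.na(v))[1]), call. = FALSE)
    d[[j]] <- v
  }
  wl <- d[[1]]
  out <- lapply(d[-1], function(a) uv_spectrum(wl, a))
  out
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  grid <- spectra[[1]]$wavelength
  for (s in spectra) if (!all(s$wavelength == grid))
    stop("spectra must share one grid to be written wide", call. = FALSE)
  d <- data.frame(wavelength_nm = grid)
  nm <- names(spectra)
  if (is.null(nm)) nm <- sprintf("spectrum_%02d", seq_along(spectra))
  for (i in seq_along(spectra)) d[[nm[i]]] <- spectra[[i]]$absorbance
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read and write measurement-graph CSV files
#'
#' Node lists (`id, name, tier, fixed_pka`) and edge lists
#' (`acid_1, acid_2, delta_pka, reliability, included, reason`) are
#' plain CSVs; missing optional columns get their defaults.
#'
#' @param nodes_path,edges_path CSV paths.
#' @param graph A [measurement_graph].
#' @param prefix Output path prefix; writes `<prefix>_nodes.csv` and
#'   `<prefix>_edges.csv`.
#' @return `read_graph_csv` returns a [measurement_graph];
#'   `write_graph_csv` returns the two paths invisibly.
#' @export
read_graph_csv <- function(nodes_path, edges_path) {
  for (p in c(nodes_path, edges_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  if ("delta_pka" %in% names(edges)) {
    v <- suppressWarnings(as.numeric(edges$delta_pka))
    if (any(is.na(v) & !is.na(edges$delta_pka)))
      stop("malformed delta_pka at row ",
           which(is.na(v) & !is.na(edges$delta_pka))[1], call. = FALSE)
    edges$delta_pka <- v
  }
  measurement_graph(nodes, edges)
}

#' @rdname read_graph_csv
#' @export
write_graph_csv <- function(graph, prefix) {
  stopifnot(inherits(graph, "measurement_graph"))
  np <- paste0(prefix, "_nodes.csv")
  ep <- paste0(prefix, "_edges.csv")
  utils::write.csv(graph$nodes, np, row.names = FALSE, na = "")
  utils::write.csv(graph$edges, ep, row.names = FALSE, na = "")
  invisible(c(nodes = np, edges = ep))
}

#' Write delta-pKa series to CSV
#'
#' @param series A `delta_pka_series` or list of them.
#' @param path Output CSV.
#' @return The summary data frame, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "delta_pka_series")) series <- list(series)
  d <- do.call(rbind, lapply(series, function(s)
    data.frame(acid_1 = s$acid_1, acid_2 = s$acid_2,
               delta_pka = s$aggregate, sd = s$within_series_sd,
               n_valid = s$n_valid, reliability = s$reliability_flag)))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(d)
}

#' Write an assigned ladder to CSV with tier-aware rounding
#'
#' Assigned values are reported to 2 decimals, except tertiary-tier
#' acids whose lower measurement reliability supports only 1 decimal.
#'
#' @param solution A `ladder_solution`.
#' @param graph The [measurement_graph] it was solved from (for
#'   tiers).
#' @param path Output CSV.
#' @param config A `run_config` controlling the rounding.
#' @return The reported data frame, invisibly.
#' @export
write_ladder_csv <- function(solution, graph, path,
                             config = default_config()) {
  tiers <- graph$nodes$tier[match(names(solution$assigned),
                                  graph$nodes$id)]
  digits <- ifelse(tiers == "tertiary", config$rounding$ladder_tertiary,
                   config$rounding$ladder)
  d <- data.frame(id = names(solution$assigned),
                  tier = tiers,
                  pka = round(solution$assigned, digits))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Run the full analysis pipeline
#'
#' Executes the stages of the weak-acid acidity analysis end to end and
#' writes a report bundle:
#'
#' 1. a seeded synthetic two-acid titration, unmixed and aggregated to
#'    a relative acidity (round trip against the known truth);
#' 2. a seeded synthetic measurement network solved by the tiered
#'    anchored least squares, with per-tier consistency values;
#' 3. the packaged compound tables: the MeCN/DMSO correlation with
#'    predictions for benzotriazole and the recommended heterocycles,
#'    both conversion equations with their prediction RMSE, the
#'    recommended-value table, and the experimental-vs-computational
#'    gas-phase acidity statistics.
#'
#' Identical config, inputs and seed give identical outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A `run_config`.
#' @param seed Integer seed for the synthetic stages.
#' @return Invisibly, a list with the stage results (`titration`,
#'   `ladder`, `correlation`, `conversions`, `recommendations`, `ga`).
#' @export
run_pipeline <- function(out_dir, config = default_config(),
                         seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(out_dir, "report.txt")
  lines <- c(sprintf("acidladder %s pipeline report",
                     as.character(utils::packageVersion("acidladder"))),
             sprintf("seed: %d", seed),
             sprintf("config hash: %s", config_hash(config)), "")

  # -- stage 1: synthetic titration round trip ------------------------
  acid_a <- acid_spec("HA", 30.00,
                      neutral_bands = data.frame(center = 320, width = 22,
                                                 height = 9000),
                      anion_bands = data.frame(center = 370, width = 26,
                                               height = 12000),
                      concentration = 1e-4)
  acid_b <- acid_spec("HB", 30.75,
                      neutral_bands = data.frame(center = 300, width = 18,
                                                 height = 8000),
                      anion_bands = data.frame(center = 420, width = 30,
                                               height = 11000),
                      concentration = 8e-5)
  plan <- titration_plan(acid_a, acid_b,
                         base_additions = seq(0.05, 0.95, by = 0.05) *
                           (1e-4 + 8e-5),
                         noise_sd = 0.005, seed = seed)
  sim <- gen_titration(plan)
  series <- unmix_titration(sim, window = config$window)
  write_series_csv(series, file.path(out_dir, "titration_series.csv"))
  lines <- c(lines, "== titration round trip ==",
             sprintf("true delta pKa %.4f, recovered %.4f (n = %d points)",
                     sim$true_delta_pka, series$aggregate, series$n_valid),
             "")

  # -- stage 2: synthetic ladder --------------------------------------
  net <- gen_network(network_plan(seed = seed + 1L))
  sol <- tiered_solve(net$graph)
  write_ladder_csv(sol, net$graph, file.path(out_dir, "ladder.csv"),
                   config)
  lines <- c(lines, "== ladder (tiered anchored least squares) ==",
             sprintf("%d acids, n_m = %d, n_c = %d, overall s = %.3f",
                     length(sol$assigned), sol$n_m, sol$n_c, sol$s),
             vapply(sol$steps, function(st)
               sprintf("  %-9s step: n_m = %3d, n_c = %3d, s = %s",
                       st$tier, st$n_m, st$n_c,
                       if (is.na(st$s)) "NA" else sprintf("%.3f", st$s)),
               character(1)),
             sprintf("mean |error| vs truth = %.4f",
                     mean(abs(sol$assigned[names(net$true_pka)] -
                                net$true_pka))), "")

  # -- stage 3: compound tables ---------------------------------------
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  t4 <- load_fixture("table4")
  corr <- fit_correlation(t2, exclude = config$correlation_exclude)
  models <- default_conversion_models()
  # the conversion benchmark set (table3 compounds, data from table2)
  conv_in <- t2[t2$name %in% t3$name, ]
  pred_nh <- apply_conversion(models$nh_specific, conv_in)
  pred_un <- apply_conversion(models$universal, conv_in)
  utils::write.csv(pred_nh, file.path(out_dir, "conversion_nh.csv"),
                   row.names = FALSE)
  utils::write.csv(pred_un, file.path(out_dir, "conversion_universal.csv"),
                   row.names = FALSE)
  rr <- config$rounding$rmse
  lines <- c(lines, "== solvent transfer ==",
             sprintf("MeCN = %.4f * DMSO + %.4f  (n = %d, fit RMSE = %.2f)",
                     corr$slope, corr$intercept, corr$n, corr$rmse_fit),
             sprintf("benzotriazole predicted from correlation: %.1f",
                     suppressWarnings(predict_linear(corr, 11.92))),
             sprintf("conversion RMSE (NH-specific): %.*f", rr,
                     prediction_rmse(pred_nh)),
             sprintf("conversion RMSE (universal):   %.*f", rr,
                     prediction_rmse(pred_un)))
  if (!isTRUE(config$water_conversion))
    lines <- c(lines,
      "water -> MeCN conversion disabled: prediction RMSE for weak acids of this type is well over 2 pKa units")
  rec <- lapply(seq_len(nrow(t4)), function(i) {
    est <- c(suppressWarnings(predict_linear(corr, t4$pka_dmso[i])),
             apply_conversion(models$nh_specific, t4[i, ])$predicted,
             apply_conversion(models$universal, t4[i, ])$predicted)
    r <- recommend_pka(est)
    data.frame(name = t4$name[i], recommended = r$mean,
               uncertainty = r$uncertainty)
  })
  rec <- do.call(rbind, rec)
  utils::write.csv(rec, file.path(out_dir, "recommended.csv"),
                   row.names = FALSE)
  lines <- c(lines, "recommended pKa(MeCN):",
             sprintf("  %-18s %.1f +- %.1f", rec$name, rec$recommended,
                     rec$uncertainty), "")
  ga <- compare_ga(t2)
  lines <- c(lines, "== gas-phase acidity comparison ==",
             sprintf("%d exp/calc pairs: rms = %d, max |diff| = %d, mean bias = %d kJ/mol",
                     nrow(ga$pairs), round(ga$rms_diff),
                     round(ga$max_abs_diff), round(ga$mean_bias)), "")

  writeLines(lines, report)
  invisible(list(titration = series, ladder = sol, correlation = corr,
                 conversions = list(nh_specific = pred_nh,
                                    universal = pred_un),
                 recommendations = rec, ga = ga, report = report))
}

# stable short hash of a config; enough to detect config drift in reports
config_hash <- function(config) {
  raw <- charToRaw(as.character(
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)))
  sprintf("%08x",
          sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max)
}
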