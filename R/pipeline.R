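# Study pipelines: polynomial-chaos sweeps over ischaemic depth,
# scenario analyses (GP + PLS per EPD pattern class), the fibre-rotation /
# depth study of the outside-minimum angle, and the sparse-grid
# level-agreement check.

.SCENARIOS <- list(
  type1 = list(depth = 0.10, target = "depression_type1",
               outputs = c("cminV", "cmaxV", "ominV", "ellipse_angle"),
               n_design = 250, n_keep = 240),
  type2 = list(depth = 0.30, target = "depression_type2",
               outputs = c("ominV", "cminV", "cmaxV", "angmin"),
               n_design = 750, n_keep = 220),
  elevation = list(depth = 0.60, target = "elevation",
                   outputs = c("cmaxV", "ominV", "angmax", "angmin"),
                   n_design = 250, n_keep = 220))

# simulator closure over a backend: f(pars, depth) -> epd
.backend <- function(backend = c("fv", "mock"), mesh = "coarse") {
  backend <- match.arg(backend)
  if (is.character(mesh)) mesh <- build_mesh(mesh)
  if (backend == "fv") function(pars, depth) simulate_epd(pars, depth, mesh)
  else function(pars, depth) mock_simulator(pars, depth)
}

#' Polynomial-chaos sweep of mean EPDs over ischaemic depth
#'
#' For each depth, varies the six bidomain conductivities on a Smolyak
#' sparse grid (fibre rotation and blood conductivity fixed) and computes
#' the weighted mean and standard-deviation EPD and the features of the
#' mean EPD.
#'
#' @param depths ischaemic depth fractions (default 0.1 to 0.6)
#' @param g_b,ROT fixed blood conductivity [mS/cm] and fibre rotation
#'   [degrees]
#' @param level sparse-grid level (default 2: 85 nodes in 6 dimensions)
#' @param mesh mesh or preset name (finite-volume backend)
#' @param backend \code{"fv"} or \code{"mock"}
#' @param ranges parameter ranges
#' @return List with \code{stats} (per-depth [pc_field_stats()] results)
#'   and \code{features} (data frame: depth, features of the mean EPD,
#'   class).
#' @export
run_pc_sweep <- function(depths = seq(0.1, 0.6, by = 0.1), g_b = 6.5,
                         ROT = 100, level = 2, mesh = "coarse",
                         backend = "fv", ranges = default_ranges()) {
  sim2 <- .backend(backend, mesh)
  grid <- smolyak_grid(6, level)
  stats <- lapply(depths, function(d) {
    sim <- function(pars) sim2(c(pars, ROT = ROT, g_b = g_b), d)
    pc_field_stats(sim, grid, ranges, vary = .CONDUCTIVITIES)
  })
  names(stats) <- paste0("depth_", depths)
  feats <- do.call(rbind, Map(function(d, s) {
    cbind(depth = d, feature_table(list(s$mean)))
  }, depths, stats))
  list(stats = stats, features = feats)
}

#' Level-2 versus level-3 sparse-grid agreement of the mean EPD
#'
#' Computes the polynomial-chaos mean EPD at both sparse-grid levels for
#' the same fixed parameters and returns their Pearson correlation and
#' relative error.  Nested nodes are shared between levels through the
#' run cache.
#'
#' @param depth ischaemic depth fraction (default 0.5)
#' @param ROT fibre rotation [degrees] (default 120)
#' @param g_b blood conductivity [mS/cm] (default 6.7)
#' @inheritParams run_pc_sweep
#' @return List with \code{correlation}, \code{relative_error}, and the
#'   two mean EPDs.
#' @export
run_level_compare <- function(depth = 0.5, ROT = 120, g_b = 6.7,
                              mesh = "small", backend = "fv",
                              ranges = default_ranges()) {
  sim2 <- .backend(backend, mesh)
  sim <- function(pars) sim2(c(pars, ROT = ROT, g_b = g_b), depth)
  s2 <- pc_field_stats(sim, smolyak_grid(6, 2), ranges)
  s3 <- pc_field_stats(sim, smolyak_grid(6, 3), ranges)
  cmp <- compare_fields(s2$mean, s3$mean)
  c(cmp, list(mean_level2 = s2$mean, mean_level3 = s3$mean))
}

#' Scenario analysis: GP emulation and PLS regression per pattern class
#'
#' Generates a Latin-hypercube design over the eight inputs at the
#' scenario's fixed depth, simulates every design point, classifies the
#' EPDs, keeps the first \code{n_keep} of the scenario's target class (in
#' generation order), and for each scenario output fits a GP emulator
#' (90/10 split, Mahalanobis validation, refit on all points), computes
#' main-effect sensitivity indices (input variance 0.02) and main-effect
#' curves (variance 0.04), and fits a NIPALS PLS regression of all outputs
#' on the standardized inputs.
#'
#' @param scenario \code{"type1"}, \code{"type2"} or \code{"elevation"}
#' @param n_design Latin-hypercube size (defaults: 250 / 750 / 250)
#' @param n_keep design rows of the target class retained (240 / 220 / 220)
#' @param mesh mesh or preset name
#' @param seed integer seed (design, GP splits, optimizer restarts)
#' @param backend \code{"fv"} or \code{"mock"}
#' @param ranges parameter ranges
#' @param main_effects also compute main-effect curves?
#' @return A \code{scenario_report}: class counts/fractions, kept design
#'   (physical and normalized), feature table, per-output GP index tables
#'   and validations, PLS coefficient table, seeds.
#' @export
run_scenario <- function(scenario = c("type1", "type2", "elevation"),
                         n_design = NULL, n_keep = NULL, mesh = "coarse",
                         seed = 1, backend = "fv", ranges = default_ranges(),
                         main_effects = FALSE) {
  scenario <- match.arg(scenario)
  sc <- .SCENARIOS[[scenario]]
  if (is.null(n_design)) n_design <- sc$n_design
  if (is.null(n_keep)) n_keep <- sc$n_keep
  sim <- .backend(backend, mesh)
  des <- latin_hypercube(n_design, ranges, seed = seed)
  phys <- denormalize(des$points, ranges)
  epds <- lapply(seq_len(n_design), function(i)
    sim(phys[i, ], sc$depth))
  feats <- feature_table(epds)
  counts <- table(factor(feats$epd_type,
                         levels = c("depression_type1", "depression_type2",
                                    "elevation")))
  hit <- which(feats$epd_type == sc$target)
  shortfall <- length(hit) < n_keep
  keep <- head(hit, n_keep)
  X <- des$points[keep, , drop = FALSE]
  Yf <- feats[keep, , drop = FALSE]
  gp <- list(); me <- list()
  for (out in sc$outputs) {
    y <- Yf[[out]]
    ok <- is.finite(y)
    fit <- gp_fit(X[ok, , drop = FALSE], y[ok], train_fraction = 0.9,
                  seed = seed)
    si <- sensitivity_indices(fit$model, others_variance = 0.02)
    gp[[out]] <- list(model = fit$model, validation = fit$validation,
                      indices = si, n_used = sum(ok))
    if (main_effects)
      me[[out]] <- lapply(seq_len(ncol(X)), function(w)
        main_effect(fit$model, w, others_variance = 0.04))
  }
  Ymat <- as.matrix(Yf[, sc$outputs, drop = FALSE])
  okr <- apply(is.finite(Ymat), 1, all)
  pls <- fit_nipals(X[okr, , drop = FALSE], Ymat[okr, , drop = FALSE])
  index_table <- do.call(rbind, lapply(gp, function(g) g$indices$indices))
  rownames(index_table) <- sc$outputs
  structure(list(
    scenario = scenario, depth = sc$depth, seed = seed,
    n_design = n_design, n_keep = length(keep), shortfall = shortfall,
    class_counts = counts, class_fractions = as.vector(counts) / n_design,
    design = phys[keep, , drop = FALSE], design_unit = X,
    features = Yf, gp = gp, index_table = index_table,
    pls = pls, pls_coefficients = t(pls$coefficients),
    main_effects = if (main_effects) me else NULL),
    class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("scenario_report '%s' (depth %.0f%%): %d/%d design rows kept\n",
              x$scenario, 100 * x$depth, x$n_keep, x$n_design))
  cat("class counts:\n"); print(x$class_counts)
  cat("GP main-effect sensitivity indices:\n")
  print(round(x$index_table, 2))
  cat("PLS standardized coefficients:\n")
  print(round(x$pls_coefficients, 2))
  invisible(x)
}

#' Write a scenario report to disk as CSV tables plus a JSON manifest
#'
#' Emits the analysis-ready artefacts of a scenario study: one CSV of
#' design inputs and extracted features (one row per kept design point),
#' CSVs of the GP sensitivity-index and PLS coefficient tables, and a JSON
#' manifest with seeds, class counts and validation verdicts.
#'
#' @param report a \code{scenario_report} from [run_scenario()]
#' @param dir output directory (created if needed)
#' @return Invisibly, the manifest path.
#' @export
save_scenario_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, report$scenario)
  utils::write.csv(cbind(report$design, report$features),
                   paste0(stem, "_design_features.csv"), row.names = FALSE)
  utils::write.csv(report$index_table, paste0(stem, "_gp_indices.csv"))
  utils::write.csv(report$pls_coefficients, paste0(stem, "_pls_coefficients.csv"))
  manifest <- list(
    scenario = report$scenario, depth = report$depth, seed = report$seed,
    n_design = report$n_design, n_keep = report$n_keep,
    shortfall = report$shortfall,
    class_counts = as.list(report$class_counts),
    validation = lapply(report$gp, function(g)
      list(D = g$validation$D, ref_mean = g$validation$ref_mean,
           ref_sd = g$validation$ref_sd, pass = g$validation$pass,
           n_used = g$n_used)))
  path <- paste0(stem, "_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Study of the outside-minimum angle versus fibre rotation and depth
#'
#' Latin-hypercube design over fibre rotation (60-140 degrees) and
#' ischaemic depth (30-80%) with all conductivities at their means; the
#' outside-minimum angle is extracted from every EPD and regressed (NIPALS
#' PLS on standardized scales) on the two inputs.
#'
#' @param n design size (default 250)
#' @param mesh mesh or preset name
#' @param seed integer seed
#' @param backend \code{"fv"} or \code{"mock"}
#' @param ranges parameter ranges
#' @return List with \code{coefficients} (named: ROT, depth), \code{data}
#'   (ROT, depth, angmin), \code{n_used}.
#' @export
run_angmin_study <- function(n = 250, mesh = "coarse", seed = 1,
                             backend = "fv", ranges = default_ranges()) {
  sim <- .backend(backend, mesh)
  rg2 <- parameter_ranges(data.frame(
    name = c("ROT", "depth"), min = c(60, 0.30),
    mean = c(100, 0.55), max = c(140, 0.80)))
  des <- latin_hypercube(n, rg2, seed = seed)
  phys <- denormalize(des$points, rg2)
  base <- default_ranges()$mean
  angs <- vapply(seq_len(n), function(i) {
    pars <- base; pars[["ROT"]] <- phys[i, "ROT"]
    f <- extract_features(sim(pars, phys[i, "depth"]))
    f$angmin
  }, numeric(1))
  ok <- is.finite(angs)
  pls <- fit_nipals(phys[ok, , drop = FALSE], angs[ok])
  co <- setNames(as.vector(pls$coefficients), rownames(pls$coefficients))
  # input-output correlations: the scale on which such studies usually
  # summarize the two relationships (full-rank standardized coefficients
  # are bounded jointly by R^2 and sit slightly lower)
  cors <- c(ROT = cor(phys[ok, "ROT"], angs[ok]),
            depth = cor(phys[ok, "depth"], angs[ok]))
  list(coefficients = co, correlations = cors,
       data = data.frame(ROT = phys[, "ROT"], depth = phys[, "depth"],
                         angmin = angs),
       n_used = sum(ok))
}
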