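#' Configure a pipeline run
#'
#' All thresholds and Monte Carlo sizes of the end-to-end analysis in one
#' validated list. Defaults are the study conditions: eligibility of at
#' least 500 animals, 5 reliable (class A/B) counts since 1989; the
#' 2002-2014 carcass window with a minimum amalgamated total of 20;
#' three GAM candidates with basis dimension 3; 1000 robustness
#' simulations; and the nested Monte Carlo sizes.
#'
#' @param input optional list with `areas`, `counts`, `carcasses` data
#'   frames (or a directory containing `areas.csv`, `counts.csv`,
#'   `carcasses.csv`); `NULL` simulates inputs from `sim_spec`.
#' @param sim_spec a [simulation_spec()] used when `input` is `NULL`.
#' @param min_pop,min_counts,min_year,reliability eligibility thresholds.
#' @param carcass_years,min_carcasses carcass amalgamation window and
#'   minimum total.
#' @param pike_covariates covariates offered to the PIKE GLM candidates.
#' @param gam_formulas,gam_k benchmark GAM candidate set and basis
#'   dimension.
#' @param robustness_n_sims count-uncertainty Monte Carlo size per series.
#' @param n_outer,n_inner nested propagation sizes.
#' @param seed master seed; every stage derives its own stream from it.
#' @param outdir optional output directory; `NULL` writes nothing.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, sim_spec = simulation_spec(),
                       min_pop = 500, min_counts = 5, min_year = 1989,
                       reliability = c("A", "B"),
                       carcass_years = 2002:2014, min_carcasses = 20,
                       pike_covariates = c("evi", "prop_12_water"),
                       gam_formulas = GAM_FORMULAS, gam_k = 3,
                       robustness_n_sims = 1000,
                       n_outer = 100, n_inner = 100,
                       seed = 1L, outdir = NULL) {
  stopifnot(min_pop > 0, min_counts > 0, min_carcasses > 0,
            robustness_n_sims > 0, n_outer > 0, n_inner > 0)
  structure(list(input = input, sim_spec = sim_spec, min_pop = min_pop,
                 min_counts = min_counts, min_year = min_year,
                 reliability = reliability, carcass_years = carcass_years,
                 min_carcasses = min_carcasses,
                 pike_covariates = pike_covariates,
                 gam_formulas = gam_formulas, gam_k = gam_k,
                 robustness_n_sims = robustness_n_sims,
                 n_outer = n_outer, n_inner = n_inner,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Validate pipeline input tables
#'
#' Checks schemas and value ranges: required columns; positive areas;
#' EVI, water proportions and empirical PIKE in `[0, 1]`; non-negative
#' estimates and SEs; no duplicated (area, year) counts; illegal carcasses
#' not exceeding totals.
#'
#' @param areas,counts,carcasses the three input data frames.
#' @return data frame of violations (`table, row, problem`); zero rows when
#'   everything is well-formed.
#' @export
validate_inputs <- function(areas, counts, carcasses) {
  v <- list()
  bad <- function(tb, rows, problem) {
    if (length(rows))
      v[[length(v) + 1]] <<- data.frame(table = tb, row = rows,
                                        problem = problem,
                                        stringsAsFactors = FALSE)
  }
  need_a <- c("area_id", "area_km2", "evi", "prop_12_water",
              "recent_estimate", "recent_year")
  miss <- setdiff(need_a, names(areas))
  bad("areas", rep(0L, length(miss)), paste("missing column", miss))
  if (!length(miss)) {
    bad("areas", which(!is.finite(areas$area_km2) | areas$area_km2 <= 0),
        "area_km2 must be > 0")
    bad("areas", which(areas$evi < 0 | areas$evi > 1), "evi outside [0, 1]")
    bad("areas", which(areas$prop_12_water < 0 | areas$prop_12_water > 1),
        "prop_12_water outside [0, 1]")
    if ("pike_empirical" %in% names(areas)) {
      pe <- areas$pike_empirical
      bad("areas", which(!is.na(pe) & (pe < 0 | pe > 1)),
          "pike_empirical outside [0, 1]")
    }
    bad("areas", which(areas$recent_estimate < 0), "negative recent_estimate")
  }
  need_c <- c("area_id", "year", "estimate", "se", "reliability")
  miss <- setdiff(need_c, names(counts))
  bad("counts", rep(0L, length(miss)), paste("missing column", miss))
  if (!length(miss)) {
    bad("counts", which(counts$estimate < 0), "negative estimate")
    bad("counts", which(counts$se < 0), "negative se")
    bad("counts", which(duplicated(counts[, c("area_id", "year")])),
        "duplicated (area_id, year)")
  }
  need_k <- c("site_id", "year", "illegal_carcasses", "total_carcasses")
  miss <- setdiff(need_k, names(carcasses))
  bad("carcasses", rep(0L, length(miss)), paste("missing column", miss))
  if (!length(miss)) {
    bad("carcasses",
        which(carcasses$illegal_carcasses > carcasses$total_carcasses),
        "illegal exceeds total")
    bad("carcasses", which(carcasses$illegal_carcasses < 0 |
                             carcasses$total_carcasses < 0),
        "negative carcass count")
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(table = character(), row = integer(), problem = character())
}

read_inputs <- function(input) {
  if (is.character(input)) {
    input <- list(
      areas = read.csv(file.path(input, "areas.csv")),
      counts = read.csv(file.path(input, "counts.csv")),
      carcasses = read.csv(file.path(input, "carcasses.csv")))
  }
  input
}

#' Run the full benchmark pipeline
#'
#' Orchestrates every stage: input simulation or loading, validation,
#' growth-model selection with count-uncertainty robustness and
#' stable-density extraction, PIKE estimation (empirical plus averaged-GLM
#' predictions for unmonitored areas), benchmark-GAM selection and
#' diagnostics, current-PIKE and zero-PIKE (ecological benchmark)
#' predictions, deficit accounting with headline summaries, and nested
#' Monte Carlo uncertainty propagation. Reruns with the same config and
#' seed are identical.
#'
#' @param config a [run_config()].
#' @return list of class `run_report` with every stage output: `inputs`,
#'   `validation`, `eligibility`, `selection_report`, `stable_densities`,
#'   `pike_estimates`, `gam_selection`, `gam_fit`, `diagnostics`,
#'   `predictions`, `deficits`, `headlines`, `mc` (propagation),
#'   `mc_summary`, `stage_counts`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  # 1. inputs
  if (is.null(config$input)) {
    sim <- generate_study_dataset(config$sim_spec)
    inputs <- sim[c("areas", "counts", "carcasses")]
    truth <- sim$truth
  } else {
    inputs <- read_inputs(config$input)
    truth <- NULL
  }
  areas <- inputs$areas
  # 2. validation
  viol <- validate_inputs(areas, inputs$counts, inputs$carcasses)
  if (nrow(viol)) stop("input validation failed:\n",
                       paste(viol$table, viol$row, viol$problem,
                             collapse = "\n"))
  # 3. growth dynamics
  elig <- filter_eligible_series(inputs$counts, config$min_pop,
                                 config$min_counts, config$min_year,
                                 config$reliability)
  trends <- extract_stable_densities(elig$eligible, areas,
                                     n_sims = config$robustness_n_sims,
                                     seed = stage_seed(config$seed, 10L))
  stable <- trends$stable_densities
  # 4. PIKE: empirical where monitored, modeled elsewhere
  amalg <- amalgamate_carcasses(inputs$carcasses, config$carcass_years)
  retained <- filter_low_carcass_sites(amalg, config$min_carcasses)
  emp <- empirical_pike(retained$illegal, retained$total, retained$site_id)
  glm_training <- cbind(retained,
                        areas[match(retained$site_id, areas$area_id),
                              config$pike_covariates, drop = FALSE])
  glm_training <- glm_training[complete.cases(glm_training), , drop = FALSE]
  pike_glm <- fit_pike_glm(glm_training, covariates = config$pike_covariates)
  unmon <- !(areas$area_id %in% emp$site_id)
  pike_est <- emp
  if (any(unmon)) {
    mod <- predict_pike(pike_glm, areas[unmon, , drop = FALSE],
                        areas$area_id[unmon])
    pike_est <- rbind(emp, mod)
  }
  m <- match(areas$area_id, pike_est$site_id)
  areas$pike <- pike_est$pike[m]
  areas$pike_eta <- pike_est$eta[m]
  areas$pike_eta_se <- pike_est$eta_se[m]
  areas$pike_source <- pike_est$source[m]
  # 5. GAM training table from null-selected series
  ti <- match(stable$area_id, areas$area_id)
  training <- data.frame(
    area_id = stable$area_id, area_km2 = areas$area_km2[ti],
    evi = areas$evi[ti], prop_12_water = areas$prop_12_water[ti],
    pike = areas$pike[ti], pike_eta = areas$pike_eta[ti],
    pike_eta_se = areas$pike_eta_se[ti],
    pike_source = areas$pike_source[ti],
    stable_density = stable$density, stable_density_se = stable$se,
    stable_size = stable$density * areas$area_km2[ti],
    log_area = log(areas$area_km2[ti]), stringsAsFactors = FALSE)
  # 6. benchmark GAM
  gsel <- select_benchmark_gam(training, config$gam_formulas, config$gam_k)
  gfit <- gsel$fits[[gsel$best_formula_id]]
  diag <- gam_diagnostics(gfit)
  # 7. scenario predictions, deficits, headlines
  pred_cur <- predict_scenario(gfit, areas)
  pred_zero <- predict_scenario(gfit, areas, pike_override = 0)
  deficits <- compute_deficits(pred_zero, areas)
  headlines <- summarize_headlines(deficits, pred_cur, areas)
  # 8. nested Monte Carlo propagation
  mc <- propagate_uncertainty(gfit, areas, n_outer = config$n_outer,
                              n_inner = config$n_inner,
                              seed = stage_seed(config$seed, 20L))
  mc_summary <- summarize_propagation(mc, min_draws = min(100,
    config$n_outer * config$n_inner))
  stage_counts <- list(
    n_areas = nrow(areas), n_series = length(unique(inputs$counts$area_id)),
    n_eligible = length(elig$eligible),
    n_null_selected = nrow(stable),
    n_mike_sites = nrow(retained),
    n_mike_excluded = length(attr(retained, "excluded")),
    n_modeled_pike = sum(areas$pike_source == "modeled"),
    gam_best = gsel$best_formula_id,
    mc_draws = nrow(mc$draws$current))
  out <- structure(list(inputs = inputs, truth = truth, validation = viol,
                        eligibility = elig$summary,
                        selection_report = trends$selection_report,
                        stable_densities = stable,
                        pike_glm = pike_glm, pike_estimates = pike_est,
                        training = training, gam_selection = gsel,
                        gam_fit = gfit, diagnostics = diag,
                        predictions = rbind(pred_cur, pred_zero),
                        deficits = deficits, headlines = headlines,
                        mc = mc, mc_summary = mc_summary,
                        stage_counts = stage_counts, config = config),
                   class = "run_report")
  if (!is.null(config$outdir)) write_outputs(out, config$outdir)
  out
}

#' @export
print.run_report <- function(x, ...) {
  sc <- x$stage_counts
  cat("Benchmark pipeline run\n")
  cat("  areas:", sc$n_areas, " eligible series:", sc$n_eligible,
      " stable (null-selected):", sc$n_null_selected, "\n")
  cat("  MIKE sites:", sc$n_mike_sites, " modeled PIKE areas:",
      sc$n_modeled_pike, "\n")
  cat("  best GAM:", sc$gam_best, " MC draws:", sc$mc_draws, "\n")
  h <- x$headlines
  cat(sprintf("  benchmark total %.0f vs recent %.0f (net deficit %.0f)\n",
              h$sum_benchmark, h$sum_recent, h$net_deficit))
  cat(sprintf("  median %% of benchmark: %.2f; %d/%d areas in deficit\n",
              h$median_pct_of_benchmark, h$n_deficit, h$n_areas))
  invisible(x)
}

#' Write stage outputs to a directory
#'
#' Writes the standard CSV outputs (`selection_report.csv`,
#' `stable_densities.csv`, `pike_estimates.csv`, `gam_selection.csv`,
#' `diagnostics.csv`, `benchmarks.csv`, `mc_summary.csv`) plus
#' `headlines.json` and `report.json` (config echo and stage counts).
#'
#' @param report a [run_pipeline()] result.
#' @param outdir directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_outputs <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(outdir, f), row.names = FALSE)
  wr(report$selection_report, "selection_report.csv")
  wr(report$stable_densities, "stable_densities.csv")
  wr(report$pike_estimates, "pike_estimates.csv")
  wr(report$gam_selection$table, "gam_selection.csv")
  wr(report$diagnostics, "diagnostics.csv")
  bench <- merge(
    report$deficits$records,
    report$predictions[report$predictions$scenario == "current_pike",
                       c("area_id", "predicted_density")],
    by = "area_id")
  wr(bench, "benchmarks.csv")
  wr(report$mc_summary, "mc_summary.csv")
  jsonlite::write_json(report$headlines,
                       file.path(outdir, "headlines.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(report$config)
  cfg$sim_spec <- NULL; cfg$input <- NULL
  jsonlite::write_json(list(config = cfg,
                            stage_counts = report$stage_counts),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
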