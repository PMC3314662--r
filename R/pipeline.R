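#' Compare scenario TNF responses against the base case
#'
#' Expresses each scenario's peak metrics relative to the base (oocyte
#' presence) run: peak height as a percentage of the base peak and the peak
#' interval (FWHM) as a fold of the base interval. The base row is by
#' construction 100% and 1.0.
#'
#' @param metrics Named list of [peak_metrics()] objects; must contain
#'   `"base"`.
#' @return A data frame with one row per scenario: `scenario`,
#'   `peak_height`, `time_to_peak`, `peak_interval`, `peak_pct_of_base`,
#'   `interval_fold_of_base`.
#' @export
compare_scenarios <- function(metrics) {
  if (!"base" %in% names(metrics))
    stop("metrics must contain a 'base' entry")
  base <- metrics[["base"]]
  if (base$peak_height <= 0) stop("base peak height must be > 0")
  rows <- lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(
      scenario = nm,
      peak_height = m$peak_height,
      time_to_peak = m$time_to_peak,
      peak_interval = m$peak_interval,
      peak_pct_of_base = 100 * m$peak_height / base$peak_height,
      interval_fold_of_base = m$peak_interval / base$peak_interval,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end chain into a run directory: (1) generate a
#' synthetic paired-design intensity table and write it as TSV; (2) lowess
#' normalization, the per-probe-set mixed model, Bonferroni control and the
#' volcano table; (3) scenario construction — from the packaged reference
#' fixtures by default, or from the synthetic data's own probe ratios; (4)
#' simulation of the base and the three response scenarios with peak metrics
#' and the scenario comparison; (5) the sensitivity report of the base
#' model. Every stage writes CSV/TSV outputs and appends to `run.log`; the
#' resolved configuration (including the seed) is written back as YAML, so a
#' run can be regenerated from its own directory.
#'
#' @param config A YAML file path or a named list. Recognized keys (all
#'   optional): `seed`, `n_probes`, `n_animals`, `noise_sd`,
#'   `planted_effects` (named list, gene -> log2 fold change), `alpha`,
#'   `lowess_span`, `use_table2_fixture` (default TRUE), `lps_dose`,
#'   `t_end`, `scenarios`.
#' @param outdir Run directory; created if absent.
#' @return Invisibly, a list with the stage outputs (`de`, `scenario_table`,
#'   `comparison`, `sensitivity`) and `outdir`.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(
    seed = 1L, n_probes = 2000L, n_animals = 3L, noise_sd = 0.25,
    planted_effects = list(), alpha = 0.05, lowess_span = 0.3,
    use_table2_fixture = TRUE, lps_dose = 1000, t_end = 360,
    scenarios = c("min_response", "avg_response", "max_response")
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  say <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = logfile,
        append = TRUE)
  }
  cat("", file = logfile)
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))

  # stage 1: synthetic data
  planted <- unlist(cfg$planted_effects)
  if (is.null(planted)) planted <- numeric(0)
  pathway_genes <- table2_scenarios()$species[1:15]
  spec <- simulation_spec(n_probes = cfg$n_probes,
                          n_animals = cfg$n_animals,
                          noise_sd = cfg$noise_sd,
                          planted_effects = planted, seed = cfg$seed)
  ann <- make_annotation(cfg$n_probes, pathway_genes)
  tab <- generate_intensities(spec, ann)
  write_probe_table(tab, file.path(outdir, "intensities.tsv"),
                    file.path(outdir, "design.tsv"))
  utils::write.table(ann, file.path(outdir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  say("simulate-data", cfg$n_probes, " probes, ", cfg$n_animals,
      " animals, noise_sd = ", cfg$noise_sd, ", seed = ", cfg$seed)

  # stage 2: differential expression
  norm <- lowess_normalize(tab, span = cfg$lowess_span)
  de <- fit_all_probe_sets(norm)
  adj <- bonferroni(de$p_raw, alpha = cfg$alpha)
  de$p_adj <- adj$p_adj
  de$significant <- adj$significant
  utils::write.csv(de, file.path(outdir, "de_results.csv"),
                   row.names = FALSE)
  utils::write.csv(volcano_table(de, alpha = cfg$alpha),
                   file.path(outdir, "volcano.csv"), row.names = FALSE)
  say("diffexpr", sum(de$significant), " of ", nrow(de),
      " probe sets significant at Bonferroni alpha = ", cfg$alpha)

  # stage 3: scenario construction
  ref <- table2_scenarios()
  if (isTRUE(cfg$use_table2_fixture)) {
    mal <- mal_ratios()
    ratio_sets <- list(MAL = mal$ratio)
    summaries <- scenario_summaries_from_reference(ref)
    summaries$MAL <- summarize_ratios(mal$ratio)
    scen <- build_scenario_table_from_summaries(summaries, ref)
  } else {
    ratio_sets <- ratio_sets_from_table(tab, ann)
    scen <- build_scenario_table(
      ratio_sets,
      sensitivities = stats::setNames(ref$sensitivity, ref$species),
      base_concs = stats::setNames(ref$base_conc, ref$species))
  }
  utils::write.csv(scen, file.path(outdir, "scenario_table.csv"),
                   row.names = FALSE)
  say("build-scenarios", nrow(scen), " species, fixtures = ",
      cfg$use_table2_fixture)

  # stage 4: simulation and comparison
  run_one <- function(scn) {
    model <- build_default_network(scen, scenario = scn,
                                   lps_dose = cfg$lps_dose)
    tc <- simulate_pathway(model, t_end = cfg$t_end)
    utils::write.csv(
      data.frame(time = tc$time, TNF = tc$concentrations[, "TNF"]),
      file.path(outdir, paste0("tnf_", scn, ".csv")), row.names = FALSE)
    peak_metrics(tc)
  }
  all_scen <- c("base", cfg$scenarios)
  metrics <- stats::setNames(lapply(all_scen, run_one), all_scen)
  comparison <- compare_scenarios(metrics)
  utils::write.csv(comparison, file.path(outdir, "scenario_comparison.csv"),
                   row.names = FALSE)
  say("compare", "peak %% of base: ",
      paste(sprintf("%s=%.1f", comparison$scenario,
                    comparison$peak_pct_of_base), collapse = ", "))

  # stage 5: sensitivity
  base_model <- build_default_network(scen, scenario = "base",
                                      lps_dose = cfg$lps_dose)
  sens <- sensitivity_report(base_model, t_end = cfg$t_end)
  utils::write.csv(sens, file.path(outdir, "sensitivity.csv"),
                   row.names = FALSE)
  say("sensitivity", "top |s|: ",
      paste(utils::head(sens$species, 3), collapse = ", "))

  invisible(list(de = de, scenario_table = scen, comparison = comparison,
                 sensitivity = sens, outdir = outdir))
}

#' Constituent ratio summaries implied by a reference scenario table
#'
#' Recovers, for every single-protein species of a reference scenario table,
#' its (min, max, geomean) expression-change summary by inverting the
#' sensitivity-sign assignment (see [summary_from_scenarios()]). This is how
#' the constituent-product rule is fed when only the published table, not
#' the underlying probe ratios, is available.
#'
#' @param ref A data frame shaped like [table2_scenarios()].
#' @return Named list, species -> `c(min, max, geomean)`.
#' @export
scenario_summaries_from_reference <- function(ref) {
  singles <- setdiff(ref$species, names(complex_definitions()))
  out <- lapply(singles, function(sp) {
    row <- ref[ref$species == sp, ]
    summary_from_scenarios(row$r_min_resp, row$r_max_resp, row$r_avg_resp,
                           row$sensitivity)
  })
  stats::setNames(out, singles)
}

#' Build a scenario table from explicit ratio summaries
#'
#' Variant of [build_scenario_table()] taking per-species (min, max,
#' geomean) summaries directly instead of raw ratio sets — single proteins
#' are assigned by sensitivity sign, complexes by the constituent-product
#' rule over the supplied summaries.
#'
#' @param summaries Named list, single-protein species ->
#'   `c(min, max, geomean)`.
#' @param ref Reference table supplying species order, base concentrations
#'   and sensitivities.
#' @param complex_defns As in [build_scenario_table()].
#' @param complex_rule As in [build_scenario_table()].
#' @return A data frame shaped like [table2_scenarios()].
#' @export
build_scenario_table_from_summaries <- function(
    summaries, ref, complex_defns = complex_definitions(),
    complex_rule = c("product", "printed")) {
  complex_rule <- match.arg(complex_rule)
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    sp <- ref$species[i]; sens <- ref$sensitivity[i]
    base <- ref$base_conc[i]
    if (sp %in% names(complex_defns)) {
      cs <- lapply(complex_defns[[sp]], function(c) summaries[[c]])
      if (any(vapply(cs, is.null, logical(1))))
        stop("missing constituent summary for complex ", sp)
      r <- complex_multipliers(cs, sens)
      if (complex_rule == "printed" && length(cs) > 2) {
        spread <- vapply(cs, function(s) s[["max"]] / s[["min"]], numeric(1))
        rd <- assign_scenarios(cs[[which.max(spread)]], sens)
        r[["r_max_resp"]] <- round2(rd[["r_max_resp"]])
        r[["r_avg_resp"]] <- round2(rd[["r_avg_resp"]])
      }
    } else {
      if (is.null(summaries[[sp]]))
        stop("missing summary for species ", sp)
      r <- round2(assign_scenarios(summaries[[sp]], sens))
    }
    data.frame(
      species = sp, base_conc = base, sensitivity = sens,
      c_min_resp = r[["r_min_resp"]] * base, r_min_resp = r[["r_min_resp"]],
      c_max_resp = r[["r_max_resp"]] * base, r_max_resp = r[["r_max_resp"]],
      c_avg_resp = r[["r_avg_resp"]] * base, r_avg_resp = r[["r_avg_resp"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
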