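test_that("ratio summaries reproduce the MAL worked example", {
  s <- summarize_ratios(mal_ratios()$ratio)
  expect_equal(round2(s[["geomean"]]), 1.08)
  expect_equal(round2(s[["max"]]), 1.51)
  expect_equal(s[["min"]], 0.7956)
  expect_equal(summarize_ratios(numeric(0)),
               c(min = 1, max = 1, geomean = 1))
  expect_equal(summarize_ratios(c(1, 1, 1)),
               c(min = 1, max = 1, geomean = 1))
  expect_error(summarize_ratios(c(1, -2)), "positive")
})

test_that("summaries are permutation-invariant, bounded and scale-equivariant", {
  set.seed(7)
  for (i in 1:20) {
    r <- exp(stats::rnorm(6, 0, 0.5))
    s <- summarize_ratios(r)
    expect_equal(s, summarize_ratios(sample(r)))
    expect_gte(s[["geomean"]], s[["min"]])
    expect_lte(s[["geomean"]], s[["max"]])
    cc <- 2.5
    expect_equal(summarize_ratios(cc * r), cc * s, tolerance = 1e-12)
  }
})

test_that("scenario assignment follows the sensitivity sign", {
  s <- c(min = 0.5, max = 2.0, geomean = 1.0)
  expect_equal(assign_scenarios(s, 0.1),
               c(r_min_resp = 0.5, r_max_resp = 2.0, r_avg_resp = 1.0))
  expect_equal(assign_scenarios(s, -0.1),
               c(r_min_resp = 2.0, r_max_resp = 0.5, r_avg_resp = 1.0))
  # MAL is inhibitory: its maximum ratio feeds the minimum-response scenario
  mal <- assign_scenarios(summarize_ratios(mal_ratios()$ratio), -1.16e-2)
  expect_equal(round2(mal[["r_min_resp"]]), 1.51)
  expect_warning(z <- assign_scenarios(s, 0), "positive")
  expect_equal(z, assign_scenarios(s, 1))
})

test_that("the constituent-product rule reproduces the dimer rows", {
  # RP1_TRIF (negative sensitivity): RP1 in [0.54, 1.64], TRIF fixed at 1
  rp1 <- summary_from_scenarios(1.64, 0.54, 0.82, -3.41e-4)
  trif <- c(min = 1, max = 1, geomean = 1)
  r <- complex_multipliers(list(rp1, trif), -2.22e-3)
  expect_equal(r, c(r_min_resp = 1.64, r_max_resp = 0.54,
                    r_avg_resp = 0.82))
  # IkB_NFkB (positive sensitivity): extreme products 0.10 and 9.85
  ikb <- summary_from_scenarios(1.79, 0.76, 1.01, -1.45e-3)
  nfkb <- summary_from_scenarios(0.13, 5.50, 1.48, 3.24e-3)
  r2 <- complex_multipliers(list(ikb, nfkb), 4.60e-1)
  expect_equal(r2[["r_min_resp"]], 0.10)
  expect_equal(r2[["r_max_resp"]], 9.85)
  # all-neutral constituents give a neutral complex
  r3 <- complex_multipliers(list(trif, trif), 0.5)
  expect_equal(r3, c(r_min_resp = 1, r_max_resp = 1, r_avg_resp = 1))
  expect_error(complex_multipliers(list(), 1), "constituent")
})

test_that("the reference scenario table is regenerated at printed precision", {
  ref <- table2_scenarios()
  summaries <- scenario_summaries_from_reference(ref)
  out <- build_scenario_table_from_summaries(summaries, ref)
  expect_identical(out$species, ref$species)
  # single-protein rows round-trip exactly
  singles <- !out$species %in% names(complex_definitions())
  for (col in c("r_min_resp", "r_max_resp", "r_avg_resp",
                "c_min_resp", "c_max_resp", "c_avg_resp"))
    expect_equal(out[[col]][singles], ref[[col]][singles])
  # dimers and the RP1_TRIF_TRAF6 triple follow the product rule exactly
  prod_rows <- out$species %in% c("IRAK4_MyD88", "RP1_TRIF", "IkB_NFkB",
                                  "RP1_TRIF_TRAF6")
  for (col in c("r_min_resp", "r_max_resp", "r_avg_resp"))
    expect_equal(out[[col]][prod_rows], ref[[col]][prod_rows])
  expect_equal(out$c_min_resp[out$species == "RP1_TRIF"], 1331.68)
  expect_equal(out$c_avg_resp[out$species == "IRAK4_MyD88"], 860.72)
  expect_equal(out$c_max_resp[out$species == "IkB_NFkB"], 98204.5)
  # IRAK1_IRAK4_MyD88: the product rule matches the printed minimum cell
  # but gives 1.81/0.68 where the published table prints 1.63/0.64
  irak <- out[out$species == "IRAK1_IRAK4_MyD88", ]
  expect_equal(irak$c_min_resp, 712)
  expect_equal(irak$r_max_resp, 1.81)
  expect_equal(irak$r_avg_resp, 0.68)
  # the compatibility switch reproduces the printed cells instead
  out_p <- build_scenario_table_from_summaries(summaries, ref,
                                               complex_rule = "printed")
  irak_p <- out_p[out_p$species == "IRAK1_IRAK4_MyD88", ]
  expect_equal(irak_p$r_max_resp, 1.63)
  expect_equal(irak_p$r_avg_resp, 0.64)
  expect_equal(irak_p$c_min_resp, 712)
})

test_that("scenario tables built from raw ratios obey ordering invariants", {
  ref <- table2_scenarios()
  sens <- stats::setNames(ref$sensitivity, ref$species)
  base <- stats::setNames(ref$base_conc, ref$species)
  set.seed(12)
  singles <- setdiff(ref$species, names(complex_definitions()))
  ratio_sets <- stats::setNames(
    lapply(singles, function(s) exp(stats::rnorm(6, 0, 0.4))), singles)
  out <- build_scenario_table(ratio_sets, sens, base)
  neg <- out$sensitivity < 0
  expect_true(all(out$r_min_resp[neg] >= out$r_max_resp[neg]))
  expect_true(all(out$r_min_resp[!neg] <= out$r_max_resp[!neg]))
  expect_true(all(out[, c("c_min_resp", "c_max_resp", "c_avg_resp")] >= 0))
  expect_error(build_scenario_table(ratio_sets, sens, base[-1],
                                    species = ref$species),
               "base concentration")
})

test_that("MAL row from the printed ratios matches the table on min and avg", {
  ref <- table2_scenarios()
  out <- build_scenario_table(
    list(MAL = mal_ratios()$ratio),
    sensitivities = stats::setNames(ref$sensitivity, ref$species),
    base_concs = stats::setNames(ref$base_conc, ref$species),
    species = "MAL")
  expect_equal(out$c_min_resp, 15100)
  expect_equal(out$r_avg_resp, 1.08)
  expect_equal(out$c_avg_resp, 10800)
  # the printed table carries 0.74 in the maximum-response cell although the
  # smallest printed ratio is 0.7956; the computed value is 0.80
  expect_equal(out$r_max_resp, 0.80)
})
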