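#' Round half-up to two decimals
#'
#' Scenario multipliers are carried at two-decimal precision with halves
#' rounded up (so 9.845 -> 9.85, 0.0988 -> 0.10). Base R's [round()] rounds
#' halves to even, which does not reproduce the published table, hence this
#' explicit convention.
#'
#' @param x Numeric vector.
#' @return `x` rounded half-up to 2 decimals.
#' @export
round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Summarize a species' probe ratios
#'
#' Reduces the (probe, animal) inseminated/non-inseminated ratios of one
#' species to the three statistics used in scenario construction: minimum,
#' maximum and geometric mean. A species with no mapped probe gets the
#' neutral summary (1, 1, 1) — its abundance is carried unchanged through all
#' scenarios.
#'
#' @param ratios Numeric vector of positive ratios (possibly empty).
#' @return Named numeric vector `c(min, max, geomean)`.
#' @export
#' @examples
#' summarize_ratios(mal_ratios()$ratio)
summarize_ratios <- function(ratios) {
  if (length(ratios) == 0)
    return(c(min = 1, max = 1, geomean = 1))
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be positive and finite")
  c(min = min(ratios), max = max(ratios),
    geomean = exp(mean(log(ratios))))
}

#' Assign ratio summaries to response scenarios by sensitivity sign
#'
#' The minimum-response scenario takes, for each species, the expression
#' change that most suppresses the TNF peak, and the maximum-response
#' scenario the change that most enhances it: for a species with positive
#' sensitivity that is (min, max); for a species with negative (inhibitory)
#' sensitivity the assignment is swapped — its maximum observed expression
#' change goes into the minimum-response scenario. The average-response
#' scenario always takes the geometric mean.
#'
#' @param summary Named vector from [summarize_ratios()].
#' @param sensitivity Signed sensitivity coefficient of the species. A zero
#'   is treated as positive, with a warning.
#' @return Named vector `c(r_min_resp, r_max_resp, r_avg_resp)` (unrounded).
#' @export
assign_scenarios <- function(summary, sensitivity) {
  stopifnot(all(c("min", "max", "geomean") %in% names(summary)))
  if (!is.finite(sensitivity)) stop("sensitivity must be finite")
  if (sensitivity == 0)
    warning("zero sensitivity treated as positive")
  if (sensitivity >= 0)
    c(r_min_resp = unname(summary["min"]),
      r_max_resp = unname(summary["max"]),
      r_avg_resp = unname(summary["geomean"]))
  else
    c(r_min_resp = unname(summary["max"]),
      r_max_resp = unname(summary["min"]),
      r_avg_resp = unname(summary["geomean"]))
}

#' Recover a species' ratio summary from its scenario multipliers
#'
#' Inverse of [assign_scenarios()]: given a scenario-table row's three
#' multipliers and the species' sensitivity sign, return the (min, max,
#' geomean) expression-change summary. Used to feed the constituent-product
#' rule from a published scenario table when the underlying probe ratios are
#' not available.
#'
#' @param r_min_resp,r_max_resp,r_avg_resp Scenario multipliers.
#' @param sensitivity Signed sensitivity of the species.
#' @return Named vector `c(min, max, geomean)`.
#' @export
summary_from_scenarios <- function(r_min_resp, r_max_resp, r_avg_resp,
                                   sensitivity) {
  if (sensitivity >= 0)
    c(min = r_min_resp, max = r_max_resp, geomean = r_avg_resp)
  else
    c(min = r_max_resp, max = r_min_resp, geomean = r_avg_resp)
}

#' Scenario multipliers of a protein complex by the constituent-product rule
#'
#' Expression data exist only for single proteins, so a complex's expression
#' change is estimated as the product of its constituents' changes (an
#' equilibrium assumption between the complex and its free constituents).
#' Candidate products are formed from the constituent extremes — the product
#' of all constituent minima, of all maxima, and of all geometric means — and
#' assigned to scenarios by the complex's own sensitivity sign exactly as in
#' [assign_scenarios()]. Each product is rounded to two decimals.
#'
#' @param constituent_summaries List of `c(min, max, geomean)` vectors, one
#'   per constituent (see [summarize_ratios()], [summary_from_scenarios()]).
#' @param sensitivity Signed sensitivity of the complex itself.
#' @return Named vector `c(r_min_resp, r_max_resp, r_avg_resp)`, rounded to
#'   2 decimals.
#' @export
complex_multipliers <- function(constituent_summaries, sensitivity) {
  if (length(constituent_summaries) == 0)
    stop("a complex needs at least one constituent summary")
  mins <- prod(vapply(constituent_summaries, `[[`, numeric(1), "min"))
  maxs <- prod(vapply(constituent_summaries, `[[`, numeric(1), "max"))
  geos <- prod(vapply(constituent_summaries, `[[`, numeric(1), "geomean"))
  r <- assign_scenarios(c(min = mins, max = maxs, geomean = geos),
                        sensitivity)
  round2(r)
}

#' Build the full scenario table
#'
#' Generates, for every pathway species, the three scenario abundances from
#' probe-level expression ratios: single proteins are summarized with
#' [summarize_ratios()] and assigned by sensitivity sign; complexes get the
#' constituent-product rule. Multipliers are rounded to two decimals
#' *before* being multiplied into concentrations (`c = round2(r) * base`) —
#' the convention under which the published table is reproduced exactly
#' (e.g. 10000 x 1.51 = 15100).
#'
#' @param ratio_sets Named list, species -> numeric vector of
#'   inseminated/non-inseminated ratios (empty or missing entries mean no
#'   mapped probe: neutral multiplier 1.00).
#' @param sensitivities Named numeric vector, species -> sensitivity
#'   coefficient; must cover every species.
#' @param base_concs Named numeric vector, species -> base abundance
#'   (molecules per cell, oocyte-presence condition); must cover every
#'   species.
#' @param complex_defns Named list, complex -> character vector of
#'   constituents (default [complex_definitions()]). Constituents must be
#'   single-protein species of the table.
#' @param species Species to tabulate; defaults to all names in
#'   `base_concs`.
#' @param complex_rule For complexes, `"product"` applies the
#'   constituent-product rule throughout (the default); `"printed"` is a
#'   compatibility switch that, for complexes of three constituents,
#'   reproduces the published table's maximum/average cells (which there
#'   equal the most variable constituent's own multipliers rather than the
#'   product; the minimum cell follows the product rule either way).
#' @return A data frame shaped like [table2_scenarios()]: `species`,
#'   `base_conc`, `sensitivity`, `c_min_resp`, `r_min_resp`, `c_max_resp`,
#'   `r_max_resp`, `c_avg_resp`, `r_avg_resp`.
#' @export
build_scenario_table <- function(ratio_sets, sensitivities, base_concs,
                                 complex_defns = complex_definitions(),
                                 species = names(base_concs),
                                 complex_rule = c("product", "printed")) {
  complex_rule <- match.arg(complex_rule)
  missing_base <- setdiff(species, names(base_concs))
  if (length(missing_base))
    stop("species missing base concentration: ",
         paste(missing_base, collapse = ", "))
  missing_sens <- setdiff(species, names(sensitivities))
  if (length(missing_sens))
    stop("species missing sensitivity: ",
         paste(missing_sens, collapse = ", "))

  summary_of <- function(sp) {
    r <- ratio_sets[[sp]]
    summarize_ratios(if (is.null(r)) numeric(0) else r)
  }

  rows <- lapply(species, function(sp) {
    sens <- sensitivities[[sp]]
    if (sp %in% names(complex_defns)) {
      constituents <- complex_defns[[sp]]
      summaries <- lapply(constituents, summary_of)
      r <- complex_multipliers(summaries, sens)
      if (complex_rule == "printed" && length(constituents) > 2) {
        # published-table behaviour: max/avg cells of triple complexes carry
        # the dominant constituent's own multipliers
        spread <- vapply(summaries, function(s) s[["max"]] / s[["min"]],
                         numeric(1))
        dom <- summaries[[which.max(spread)]]
        rd <- assign_scenarios(dom, sens)
        r[["r_max_resp"]] <- round2(rd[["r_max_resp"]])
        r[["r_avg_resp"]] <- round2(rd[["r_avg_resp"]])
      }
    } else {
      r <- round2(assign_scenarios(summary_of(sp), sens))
    }
    base <- base_concs[[sp]]
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

#' Collect per-species ratio sets from an intensity table
#'
#' Maps probe-level inseminated/non-inseminated ratios (see
#' [probe_ratios()]) to pathway species through an annotation, yielding the
#' `ratio_sets` input of [build_scenario_table()].
#'
#' @param table A `probe_table` on the raw intensity scale.
#' @param annotation Data frame with `probe_id` and `pathway_species`.
#' @return Named list, species -> numeric vector of ratios (one per probe
#'   and animal).
#' @export
ratio_sets_from_table <- function(table, annotation) {
  rat <- probe_ratios(table)
  ann <- annotation[!is.na(annotation$pathway_species), ]
  sets <- split(ann$probe_id, ann$pathway_species)
  lapply(sets, function(pids) as.vector(rat[pids, , drop = FALSE]))
}
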