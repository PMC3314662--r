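#' Construct a mass-action pathway model
#'
#' A pathway model is a list of species with initial abundances (molecules
#' per cell), a list of irreversible mass-action reactions, a stimulus
#' specification and a readout species. Reaction rates follow the law of
#' mass action: `v = k * prod(reactant^stoichiometry)`; the species balance
#' is rate of accumulation = total production - total consumption.
#'
#' @param species Named numeric vector of initial abundances (molecules per
#'   cell); all >= 0.
#' @param reactions List of reactions; each a list with `reactants` and
#'   `products` (named stoichiometry vectors over species; either may be
#'   empty for synthesis/degradation) and a non-negative rate constant `k`
#'   (units min^-1 times (molecules/cell)^(1 - total reactant order)).
#' @param stimulus List with `species`, `dose` (molecules per cell) and
#'   `time` (minutes; the dose is added to the species at this onset, default
#'   0, i.e. present from the start).
#' @param readout Species whose trajectory is the model output (TNF in the
#'   default network).
#' @return An object of class `pathway_model`.
#' @export
pathway_model <- function(species, reactions,
                          stimulus = list(species = "LPS", dose = 0,
                                          time = 0),
                          readout = "TNF") {
  if (is.null(names(species)) || any(names(species) == ""))
    stop("species must be a fully named vector")
  if (any(species < 0)) stop("initial abundances must be >= 0")
  if (!readout %in% names(species)) stop("readout species not in model")
  if (!stimulus$species %in% names(species))
    stop("stimulus species not in model")
  for (r in reactions) {
    if (is.null(r$k) || r$k < 0) stop("rate constants must be >= 0")
    unknown <- setdiff(c(names(r$reactants), names(r$products)),
                       names(species))
    if (length(unknown))
      stop("reaction references unknown species: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(species = species, reactions = reactions,
                 stimulus = stimulus, readout = readout),
            class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf(
    "pathway_model: %d species, %d reactions; stimulus %s = %g, readout %s\n",
    length(x$species), length(x$reactions), x$stimulus$species,
    x$stimulus$dose, x$readout))
  invisible(x)
}

rxn <- function(reactants, products, k, name = NULL) {
  list(reactants = reactants, products = products, k = k, name = name)
}

#' Default rate constants of the reduced TLR4 network
#'
#' The version-pinned rate-constant set of [build_default_network()].
#' Second-order constants are in (molecules/cell)^-1 min^-1, first-order in
#' min^-1. They are package defaults chosen to yield a single transient TNF
#' peak within a 360-minute horizon under the default LPS dose, not
#' literature measurements; the published full model's constants are not
#' public, so quantitative peak percentages are not comparable (see the
#' methods vignette).
#'
#' @return Named numeric vector of rate constants.
#' @export
default_rate_constants <- function() {
  c(
    k_lps_cd14   = 5e-5,  # LPS capture by CD14
    k_md2        = 5e-5,  # MD2 joins the LPS:CD14 complex
    k_tlr4       = 5e-5,  # TLR4 engagement -> active receptor
    k_tram       = 2e-5,  # productive TRAM-branch engagement
    k_mal        = 2e-5,  # MAL sequesters the active receptor (dead end)
    k_r_int      = 0.05,  # receptor internalization
    k_rt_int     = 0.02,  # TRAM-engaged receptor internalization
    k_trif_act   = 1e-5,  # TRIF activation at the TRAM-engaged receptor
    k_rp1_bind   = 1e-4,  # active TRIF recruits RP1
    k_rp1trif_rec  = 1e-6, # recruitment of the preformed RP1_TRIF pool
    k_traf6_bind = 1e-5,  # TRAF6 joins active RP1_TRIF
    k_rtt_rec    = 1e-6,  # recruitment of the preformed RP1_TRIF_TRAF6 pool
    k_tak1_trif  = 1e-5,  # TAK1 activation by the TRIF-branch complex
    k_myd88_act  = 1e-5,  # MyD88 activation at the active receptor
    k_irak4_bind = 1e-4,  # IRAK4 joins active MyD88
    k_im_rec     = 1e-6,  # recruitment of the preformed IRAK4_MyD88 pool
    k_irak1_bind = 1e-5,  # IRAK1 joins the active IRAK4:MyD88 complex
    k_iim_rec    = 1e-6,  # recruitment of the preformed IRAK1_IRAK4_MyD88 pool
    k_traf6_act  = 1e-6,  # TRAF6 activation by the MyD88-branch complex
    k_tak1_myd   = 1e-5,  # TAK1 activation by active TRAF6
    k_ikk_act    = 1e-4,  # IKK activation by active TAK1
    k_nfkb_rel   = 1e-6,  # IKK-driven IkB degradation in the IkB:NFkB pool
    k_nfkb_act   = 1e-6,  # IKK-driven activation of the free NFkB pool
    k_ikb_deg    = 1e-5,  # IKK-driven degradation of free IkB-alpha
    k_nfkb_bind  = 1e-3,  # IkB-alpha recaptures nuclear NFkB (neg. feedback)
    k_nfkb_exp   = 0.04,  # nuclear export of NFkB back to the free pool
    k_pro_on     = 0.05,  # nuclear NFkB engages a free TNF transcription site
    k_pro_cat    = 10,    # transcribing site releases NFkB_n and emits TNF
    k_ikb_syn    = 0.05,  # NFkB-driven IkB-alpha resynthesis
    k_tnf_deg    = 0.02,  # first-order TNF decay
    k_act_decay  = 0.05   # deactivation of transient active species
  )
}

#' Build the default reduced TLR4 signalling network
#'
#' Assembles a deterministic mass-action model over the 20 scenario-table
#' species plus LPS, TNF and the transient activated intermediates. The
#' topology follows the canonical TLR4 wiring: LPS is captured by
#' CD14, MD2 and TLR4 into an active receptor; the receptor engages TRAM
#' (productive, leading via TRIF/RP1/TRAF6 to TAK1) or MAL (modeled as a
#' sequestering, non-productive engagement, which gives MAL its net
#' inhibitory effect on the TNF peak — a topology choice of this package);
#' the MyD88 branch assembles IRAK4/IRAK1 complexes that activate TRAF6;
#' both branches converge on TAK1 -> IKK; active IKK liberates NFkB into its
#' nuclear (transcriptionally active) form, both from the IkB:NFkB pool (by
#' degrading the bound IkB) and from the free cytoplasmic NFkB pool, and
#' degrades free IkB-alpha; nuclear NFkB drives TNF synthesis and IkB-alpha
#' resynthesis, and recapture of nuclear NFkB by IkB-alpha is the negative
#' feedback that terminates the response once IKK activity wanes. Preformed complex pools (IRAK4_MyD88,
#' IRAK1_IRAK4_MyD88, RP1_TRIF, RP1_TRIF_TRAF6) are inactive reservoirs that
#' active receptors can recruit, so nothing signals without stimulus.
#'
#' @param scenario_table A data frame shaped like [table2_scenarios()],
#'   covering all 20 pathway species.
#' @param scenario Which abundance column seeds the initial conditions:
#'   `"base"` (oocyte presence) or the embryo-presence scenarios
#'   `"min_response"`, `"max_response"`, `"avg_response"`.
#' @param lps_dose LPS stimulus, molecules per cell, present from t = 0.
#' @param rate_constants Named vector as [default_rate_constants()].
#' @param tnf_sites Size of the finite pool of TNF transcription sites
#'   (molecules per cell); the ceiling `k_pro_cat * tnf_sites` on the TNF
#'   synthesis flux is what lets strong scenarios broaden rather than merely
#'   scale the response.
#' @return A `pathway_model` with readout `"TNF"`.
#' @export
build_default_network <- function(scenario_table = table2_scenarios(),
                                  scenario = c("base", "min_response",
                                               "max_response",
                                               "avg_response"),
                                  lps_dose = 1000,
                                  rate_constants = default_rate_constants(),
                                  tnf_sites = 50) {
  scenario <- match.arg(scenario)
  col <- switch(scenario, base = "base_conc", min_response = "c_min_resp",
                max_response = "c_max_resp", avg_response = "c_avg_resp")
  needed <- table2_scenarios()$species
  missing <- setdiff(needed, scenario_table$species)
  if (length(missing))
    stop("scenario table missing species: ", paste(missing, collapse = ", "))
  init <- stats::setNames(scenario_table[[col]], scenario_table$species)
  init <- init[needed]

  k <- rate_constants
  intermediates <- c("LPS_CD14", "LPS_CD14_MD2", "R_active", "R_TRAM",
                     "R_MAL", "TRIF_active", "RP1_TRIF_active",
                     "RP1_TRIF_TRAF6_active", "MyD88_active",
                     "IRAK4_MyD88_active", "IRAK1_IRAK4_MyD88_active",
                     "TRAF6_active", "TAK1_active", "IKK_active", "NFkB_n")
  species <- c(LPS = lps_dose, init,
               stats::setNames(rep(0, length(intermediates)), intermediates),
               TNF_site = tnf_sites, TNF_txn = 0, TNF = 0)

  one <- function(...) {
    v <- c(...); stats::setNames(rep(1, length(v)), v)
  }
  reactions <- list(
    # receptor activation
    rxn(one("LPS", "CD14"), one("LPS_CD14"), k[["k_lps_cd14"]]),
    rxn(one("LPS_CD14", "MD2"), one("LPS_CD14_MD2"), k[["k_md2"]]),
    rxn(one("LPS_CD14_MD2", "TLR4"), one("R_active"), k[["k_tlr4"]]),
    rxn(one("R_active", "TRAM"), one("R_TRAM"), k[["k_tram"]]),
    rxn(one("R_active", "MAL"), one("R_MAL"), k[["k_mal"]]),
    rxn(one("R_active"), numeric(0), k[["k_r_int"]]),
    rxn(one("R_TRAM"), numeric(0), k[["k_rt_int"]]),
    # TRIF branch
    rxn(one("R_TRAM", "TRIF"), one("R_TRAM", "TRIF_active"),
        k[["k_trif_act"]]),
    rxn(one("TRIF_active", "RP1"), one("RP1_TRIF_active"),
        k[["k_rp1_bind"]]),
    rxn(one("R_TRAM", "RP1_TRIF"), one("R_TRAM", "RP1_TRIF_active"),
        k[["k_rp1trif_rec"]]),
    rxn(one("RP1_TRIF_active", "TRAF6"), one("RP1_TRIF_TRAF6_active"),
        k[["k_traf6_bind"]]),
    rxn(one("R_TRAM", "RP1_TRIF_TRAF6"),
        one("R_TRAM", "RP1_TRIF_TRAF6_active"), k[["k_rtt_rec"]]),
    rxn(one("RP1_TRIF_TRAF6_active", "TAK1"),
        one("RP1_TRIF_TRAF6_active", "TAK1_active"), k[["k_tak1_trif"]]),
    # MyD88 branch
    rxn(one("R_active", "MyD88"), one("R_active", "MyD88_active"),
        k[["k_myd88_act"]]),
    rxn(one("MyD88_active", "IRAK4"), one("IRAK4_MyD88_active"),
        k[["k_irak4_bind"]]),
    rxn(one("R_active", "IRAK4_MyD88"),
        one("R_active", "IRAK4_MyD88_active"), k[["k_im_rec"]]),
    rxn(one("IRAK4_MyD88_active", "IRAK1"),
        one("IRAK1_IRAK4_MyD88_active"), k[["k_irak1_bind"]]),
    rxn(one("R_active", "IRAK1_IRAK4_MyD88"),
        one("R_active", "IRAK1_IRAK4_MyD88_active"), k[["k_iim_rec"]]),
    rxn(one("IRAK1_IRAK4_MyD88_active", "TRAF6"),
        one("IRAK1_IRAK4_MyD88_active", "TRAF6_active"),
        k[["k_traf6_act"]]),
    # convergence on TAK1 -> IKK -> NFkB
    rxn(one("TRAF6_active", "TAK1"), one("TRAF6_active", "TAK1_active"),
        k[["k_tak1_myd"]]),
    rxn(one("TAK1_active", "Ikk_Complex"), one("TAK1_active", "IKK_active"),
        k[["k_ikk_act"]]),
    rxn(one("IKK_active", "IkB_NFkB"), one("IKK_active", "NFkB_n"),
        k[["k_nfkb_rel"]]),
    rxn(one("IKK_active", "NFkB"), one("IKK_active", "NFkB_n"),
        k[["k_nfkb_act"]]),
    rxn(one("IKK_active", "IkB-alpha"), one("IKK_active"),
        k[["k_ikb_deg"]]),
    rxn(one("NFkB_n", "IkB-alpha"), one("IkB_NFkB"), k[["k_nfkb_bind"]]),
    rxn(one("NFkB_n"), one("NFkB"), k[["k_nfkb_exp"]]),
    # readout: TNF transcription through a finite pool of sites, so TNF
    # output saturates at high nuclear NFkB; feedback IkB synthesis
    rxn(one("NFkB_n", "TNF_site"), one("TNF_txn"), k[["k_pro_on"]]),
    rxn(one("TNF_txn"), one("TNF_site", "NFkB_n", "TNF"),
        k[["k_pro_cat"]]),
    rxn(one("NFkB_n"), one("NFkB_n", "IkB-alpha"), k[["k_ikb_syn"]]),
    rxn(one("TNF"), numeric(0), k[["k_tnf_deg"]]),
    # deactivation of transient species
    rxn(one("TRIF_active"), numeric(0), k[["k_act_decay"]]),
    rxn(one("MyD88_active"), numeric(0), k[["k_act_decay"]]),
    rxn(one("IRAK4_MyD88_active"), numeric(0), k[["k_act_decay"]]),
    rxn(one("IRAK1_IRAK4_MyD88_active"), numeric(0), k[["k_act_decay"]]),
    rxn(one("RP1_TRIF_active"), numeric(0), k[["k_act_decay"]]),
    rxn(one("RP1_TRIF_TRAF6_active"), numeric(0), k[["k_act_decay"]]),
    rxn(one("TRAF6_active"), numeric(0), k[["k_act_decay"]]),
    rxn(one("TAK1_active"), numeric(0), k[["k_act_decay"]]),
    rxn(one("IKK_active"), numeric(0), k[["k_act_decay"]])
  )
  pathway_model(species, reactions,
                stimulus = list(species = "LPS", dose = lps_dose, time = 0),
                readout = "TNF")
}

#' Integrate a pathway model
#'
#' Builds the mass-balance ODE system of the model (accumulation =
#' production - consumption under mass-action kinetics) and integrates it
#' with the stiff-capable adaptive solver [deSolve::lsoda()] on a dense
#' output grid.
#'
#' @param model A `pathway_model`.
#' @param t_end Simulation horizon, minutes (> 0).
#' @param rel_tol,abs_tol Integrator tolerances (> 0).
#' @param dt Output grid spacing, minutes.
#' @return An object of class `time_course`: list with `time` (minutes) and
#'   `concentrations` (matrix, time x species).
#' @export
simulate_pathway <- function(model, t_end = 360, rel_tol = 1e-8,
                             abs_tol = 1e-8, dt = 0.5) {
  stopifnot(inherits(model, "pathway_model"))
  if (t_end <= 0) stop("t_end must be > 0")
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be > 0")

  sp <- names(model$species)
  n_rxn <- length(model$reactions)
  S <- matrix(0, length(sp), n_rxn, dimnames = list(sp, NULL))
  react_idx <- vector("list", n_rxn)
  react_st <- vector("list", n_rxn)
  kvec <- numeric(n_rxn)
  for (j in seq_len(n_rxn)) {
    r <- model$reactions[[j]]
    kvec[j] <- r$k
    if (length(r$reactants)) {
      S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
      react_idx[[j]] <- match(names(r$reactants), sp)
      react_st[[j]] <- unname(r$reactants)
    } else {
      react_idx[[j]] <- integer(0)
      react_st[[j]] <- numeric(0)
    }
    if (length(r$products))
      S[names(r$products), j] <- S[names(r$products), j] + r$products
  }

  rhs <- function(t, x, parms) {
    xc <- pmax(x, 0)
    v <- kvec
    for (j in seq_len(n_rxn)) {
      idx <- react_idx[[j]]
      if (length(idx)) v[j] <- v[j] * prod(xc[idx]^react_st[[j]])
    }
    list(as.vector(S %*% v))
  }

  x0 <- model$species
  if (!is.null(model$stimulus) && model$stimulus$time == 0)
    x0[model$stimulus$species] <- model$stimulus$dose
  times <- seq(0, t_end, by = dt)
  out <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                        rtol = rel_tol, atol = abs_tol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(out, "istate")[1], ")")
  conc <- unname(out[, -1, drop = FALSE])
  colnames(conc) <- sp
  if (min(conc) < -1e-6 * max(abs(conc)))
    stop("negative concentrations beyond tolerance: min = ", min(conc))
  structure(list(time = out[, 1], concentrations = conc,
                 readout = model$readout),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("time_course: %d species over [%g, %g] min (%d points)\n",
              ncol(x$concentrations), min(x$time), max(x$time),
              length(x$time)))
  invisible(x)
}

#' Write a time course as CSV
#'
#' @param tc A `time_course`.
#' @param path Output CSV path (column `time` plus one column per species).
#' @export
write_time_course <- function(tc, path) {
  df <- data.frame(time = tc$time, tc$concentrations, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Peak metrics of a readout trajectory
#'
#' The peak height H is the trajectory maximum, refined by a local quadratic
#' fit through the grid maximum and its neighbours; the peak interval W is
#' the full width at half maximum — the width of the interval on which the
#' readout is at least H/2, with the crossings located by linear
#' interpolation.
#'
#' @param tc A `time_course`.
#' @param readout Species to measure; defaults to the model readout.
#' @return An object of class `peak_metrics`: list with `peak_height`,
#'   `time_to_peak`, `peak_interval` (FWHM, NA when undefined), and flags
#'   `flat` (identically zero trajectory) and `non_transient` (maximum at
#'   the end of the horizon, no descending flank).
#' @export
peak_metrics <- function(tc, readout = NULL) {
  stopifnot(inherits(tc, "time_course"))
  if (is.null(readout)) readout <- tc$readout
  if (!readout %in% colnames(tc$concentrations))
    stop("readout not present in time course: ", readout)
  y <- tc$concentrations[, readout]
  t <- tc$time
  if (all(y == 0))
    return(structure(list(peak_height = 0, time_to_peak = NA_real_,
                          peak_interval = NA_real_, flat = TRUE,
                          non_transient = FALSE), class = "peak_metrics"))
  i <- which.max(y)
  H <- y[i]; tp <- t[i]
  if (i > 1 && i < length(y)) {
    # quadratic refinement through the grid maximum and neighbours
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      d <- 0.5 * (y1 - y3) / denom
      tp <- t[i] + d * (t[i + 1] - t[i])
      H <- y2 - 0.25 * (y1 - y3) * d
    }
  }
  non_transient <- i == length(y)
  half <- H / 2
  W <- NA_real_
  if (!non_transient) {
    above <- y >= half
    first <- which(above)[1]
    last <- rev(which(above))[1]
    t_left <- if (first == 1) t[1] else {
      stats::approx(y[(first - 1):first], t[(first - 1):first],
                    xout = half)$y
    }
    t_right <- if (last == length(y)) t[length(y)] else {
      stats::approx(y[last:(last + 1)], t[last:(last + 1)], xout = half)$y
    }
    W <- t_right - t_left
  }
  structure(list(peak_height = unname(H), time_to_peak = unname(tp),
                 peak_interval = unname(W), flat = FALSE,
                 non_transient = non_transient), class = "peak_metrics")
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat(sprintf(
    "peak_metrics: H = %.4g, time to peak = %.4g min, FWHM = %.4g min%s\n",
    x$peak_height, x$time_to_peak, x$peak_interval,
    if (x$non_transient) " [non-transient]" else ""))
  invisible(x)
}
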