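# Internal: restore the caller's RNG state on exit so seeded simulations do
# not perturb user-level randomness.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default coculture scenario
#'
#' Returns a [CocultureScenario-class] parameterized to emulate the study
#' conditions of an air-bubbled minimal-medium alga/rhizobium coculture:
#' an algal plateau near 4e6 cells/ml under either light regime (cultures
#' inoculated to reach the same final algal density, so the diurnal
#' inoculum is larger), 13CO2 label from 13 h, half the medium ammonium as
#' 99 atom% 15N, roughly 2% of the algal population lysing per 48 h, 100
#' CFU of bacterial growth supported per lysed algal cell, and greater
#' photosynthate exudation under continuous light. With these defaults the
#' continuous-light run supports about 3-fold more bacterial cells than
#' the diurnal run.
#'
#' @param lightRegime `"continuous"` or `"diurnal_12_12"`.
#' @param seed integer seed driving all generator randomness.
#' @param ... named scenario slots to override (see
#'   [CocultureScenario-class]).
#' @return a validated [CocultureScenario-class].
#' @examples
#' defaultScenario("continuous", seed = 7)
#' @export
defaultScenario <- function(lightRegime = c("continuous", "diurnal_12_12"),
                            seed = 1L, ...) {
  lightRegime <- match.arg(lightRegime)
  diurnal <- lightRegime == "diurnal_12_12"
  args <- list(
    lightRegime = lightRegime,
    durationH = 72,
    algalN0 = if (diurnal) 1e6 else 2.5e5,
    algalK = 4e6,
    algalDoublingH = 8,
    bacterialN0 = 1e6,
    exudationRate = if (diurnal) 0.04 else 0.137,
    lysisFractionPerDay = 0.008,
    bacterialYieldPerLysedCell = 100,
    bacterialYieldPerUgNPOC = 1.4e6,
    bacterialGrowthRate = 0.12,
    biomassYieldFactor = 0.012,
    reductiveDivisionMax = 3,
    labelStartH = 13,
    f15NSubstrate = 0.5 * 0.99 + 0.5 * (0.00367 / 1.00367),
    f13CSourceMax = 0.35,
    b12OnsetH = 24,
    cellLengthMaxUm = 2.3,
    cellLengthMinUm = 1.25,
    seed = as.integer(seed)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(args))
  if (length(bad)) stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  args[names(over)] <- over
  args$seed <- as.integer(args$seed)
  do.call(new, c(list(Class = "CocultureScenario"), args))
}

#' Simulate a phototroph-heterotroph coculture
#'
#' Integrates a seeded dynamical model of the coculture and returns the
#' growth series, a carbon-pool ledger, and a per-cell ground-truth table
#' for downstream recovery tests. The model:
#'
#' * Algae grow logistically (continuous light) or divide synchronously
#'   once at each dark-phase onset (diurnal), toward carrying capacity
#'   `algalK`. A constant fraction of the population lyses per day.
#' * Live algal cells exude dissolved organic carbon (NPOC) during light
#'   hours at `exudationRate`.
#' * Bacteria grow on the released carbon pool (necromass plus exudate,
#'   expressed in CFU equivalents via the two yield parameters) with
#'   Monod-limited uptake, so cumulative bacterial proliferation can never
#'   exceed cumulative carbon release.
#' * New bacterial biomass per new CFU is `biomassYieldFactor` inoculum
#'   cell equivalents; values well below 1 reproduce the starvation
#'   mismatch in which colony counts multiply while biomass barely grows
#'   (reductive division), with mean cell length shrinking accordingly.
#' * Isotope truth: algal carbon fixed after `labelStartH` carries
#'   `f13CSourceMax` atom fraction 13C; bacterial new biomass carries the
#'   concurrent algal composition (its carbon source) and medium-ammonium
#'   15N at `f15NSubstrate`. So bacterial 13C enrichment approaches a
#'   fixed fraction of the algal enrichment set by the new-biomass
#'   fraction.
#'
#' @param scenario a [CocultureScenario-class].
#' @param timepointsH sampling times for the growth series, hours.
#' @param sipTimepointsH timepoints at which single cells are "measured"
#'   into the truth table (default `c(12, 24, 36, 48)`).
#' @param nReplicates replicate cultures in the growth series (default 4,
#'   quadruplicate cultures as in the growth experiments).
#' @param sipReplicates replicate cultures sampled into the single-cell
#'   truth table (default 2, duplicate SIP cocultures).
#' @param cellsPerTimepoint named vector: truth-table cells per partner
#'   per timepoint per culture (defaults: 10 algae, 12 bacteria, at least
#'   the 5-10 measurable cells per partner a field analysis yields).
#' @param dtH Euler integration step, hours.
#' @return list with elements `growth` ([GrowthSeries-class]), `ledger`
#'   (data.frame of per-step population, carbon-pool, and truth-state
#'   trajectories), `truth` (data.frame: `cell_id`, `culture`, `partner`,
#'   `timepoint_h`, `true_p13C`, `true_p15N`, `true_length_um`), and
#'   `scenario`.
#' @examples
#' sim <- simulateCoculture(defaultScenario("continuous", seed = 1))
#' max(subset(growthData(sim$growth), partner == "alga")$density)
#' @export
simulateCoculture <- function(scenario,
                              timepointsH = seq(0, scenario@durationH, by = 6),
                              sipTimepointsH = c(12, 24, 36, 48),
                              nReplicates = 4L,
                              sipReplicates = 2L,
                              cellsPerTimepoint = c(alga = 10L, bacterium = 12L),
                              dtH = 0.05) {
  validObject(scenario)
  if (any(timepointsH < 0) || any(!is.finite(timepointsH)))
    stop("timepointsH must be finite and >= 0")
  if (any(sipTimepointsH < 0)) stop("sipTimepointsH must be >= 0")
  sc <- scenario
  diurnal <- sc@lightRegime == "diurnal_12_12"
  tgrid <- seq(0, sc@durationH, by = dtH)
  n <- length(tgrid)
  lightOn <- if (diurnal) (tgrid %% 24) < 12 else rep(TRUE, n)

  r <- log(2) / sc@algalDoublingH
  lysPerH <- sc@lysisFractionPerDay / 24
  natC <- 0.02247 / 2.02247   # natural 13C atom fraction (dimer standard)
  natN <- 0.00367 / 1.00367

  A <- numeric(n); A[1] <- sc@algalN0
  Abio <- numeric(n); Abio[1] <- sc@algalN0   # biomass proxy for labeling
  L <- numeric(n)                             # cumulative lysed cells/ml
  E <- numeric(n)                             # cumulative exuded NPOC ug/ml
  B <- numeric(n); B[1] <- sc@bacterialN0
  S <- numeric(n)                             # unconsumed pool, CFU equiv
  supply <- numeric(n)                        # cumulative release, CFU equiv
  pAlga <- numeric(n); pAlga[1] <- natC
  pBactC <- numeric(n); pBactC[1] <- natC
  labIntegral <- 0                            # integral of pAlga over consumption
  AbioLab <- NA_real_

  for (i in 2:n) {
    t0 <- tgrid[i - 1]; t1 <- tgrid[i]
    # --- algae ---
    lys <- lysPerH * A[i - 1] * dtH
    if (diurnal) {
      grew <- 0
      # synchronized division at dark onset (first step past hour 12 of day)
      if ((t0 %% 24) < 12 && (t1 %% 24) >= 12) {
        grew <- min(A[i - 1], sc@algalK - A[i - 1])
        grew <- max(grew, 0)
      }
      A[i] <- A[i - 1] + grew - lys
      # biomass accrues during light toward the division
      bioGrow <- if (lightOn[i - 1] && Abio[i - 1] < sc@algalK)
        log(2) / 12 * Abio[i - 1] * dtH else 0
      bioGrow <- min(bioGrow, max(sc@algalK - Abio[i - 1], 0))
      Abio[i] <- Abio[i - 1] + bioGrow
    } else {
      dA <- r * A[i - 1] * (1 - A[i - 1] / sc@algalK) * dtH
      A[i] <- A[i - 1] + dA - lys
      Abio[i] <- Abio[i - 1] + max(dA, 0)
    }
    L[i] <- L[i - 1] + lys
    dE <- if (lightOn[i - 1]) sc@exudationRate * (A[i - 1] / 1e6) * dtH else 0
    E[i] <- E[i - 1] + dE
    # --- algal 13C truth ---
    if (is.na(AbioLab) && t1 >= sc@labelStartH) AbioLab <- Abio[i]
    fNew <- if (is.na(AbioLab)) 0 else max(0, 1 - AbioLab / Abio[i])
    pAlga[i] <- natC + fNew * (sc@f13CSourceMax - natC)
    # --- bacteria: Monod uptake of released carbon ---
    dSupply <- sc@bacterialYieldPerLysedCell * lys + sc@bacterialYieldPerUgNPOC * dE
    supply[i] <- supply[i - 1] + dSupply
    avail <- S[i - 1] + dSupply
    Ks <- 2e6
    dB <- sc@bacterialGrowthRate * B[i - 1] * avail / (Ks + avail) * dtH
    dB <- min(dB, avail)
    B[i] <- B[i - 1] + dB
    S[i] <- avail - dB
    labIntegral <- labIntegral + (pAlga[i] - natC) * dB
    M <- sc@bacterialN0 + sc@biomassYieldFactor * (B[i] - sc@bacterialN0)
    pBactC[i] <- natC + sc@biomassYieldFactor * labIntegral / M
  }

  M <- sc@bacterialN0 + sc@biomassYieldFactor * (B - sc@bacterialN0)
  nuNew <- (M - sc@bacterialN0) / M              # new-biomass fraction
  pBactN <- nuNew * sc@f15NSubstrate + (1 - nuNew) * natN
  # algal 15N: new biomass since inoculation assimilates medium ammonium
  nuAlga <- pmax(0, 1 - Abio[1] / Abio)
  pAlgaN <- nuAlga * sc@f15NSubstrate + (1 - nuAlga) * natN
  # starvation allometry: mean length tracks per-capita biomass, floored by
  # the reductive-division limit
  relBiomass <- pmax(M / B, 2^(-sc@reductiveDivisionMax))
  # pole-to-pole length scales with the square root of per-capita biomass
  # (rod width shrinks alongside length under starvation), floored by the
  # reductive-division limit
  lenT <- pmax(sc@cellLengthMinUm, sc@cellLengthMaxUm * sqrt(relBiomass))
  b12 <- pmax(0, cumsum((tgrid >= sc@b12OnsetH) * B * dtH)) * 2e-8  # ng/l

  ledger <- data.frame(
    time_h = tgrid,
    algal_cells_ml = A,
    bacterial_cfu_ml = B,
    cum_lysed_cells_ml = L,
    cum_exuded_npoc_ug_ml = E,
    cum_carbon_supply_cfu_eq = supply,
    cum_carbon_consumed_cfu_eq = B - B[1],
    carbon_pool_cfu_eq = S,
    algal_f13c = pAlga,
    algal_f15n = pAlgaN,
    bacterial_f13c = pBactC,
    bacterial_f15n = pBactN,
    bacterial_new_biomass_fraction = nuNew,
    mean_bacterial_length_um = lenT,
    b12_ng_per_l = b12
  )

  at <- function(tp, col) stats::approx(tgrid, ledger[[col]], xout = tp,
                                        rule = 2)$y
  # regime-specific stream so paired runs at one seed stay independent
  seedEff <- sc@seed + if (diurnal) 1000003L else 0L
  .withSeed(seedEff, {
    obs <- do.call(rbind, lapply(seq_len(nReplicates), function(rep) {
      noise <- function(x) x * exp(stats::rnorm(length(x), 0, 0.05))
      rbind(
        data.frame(time_h = timepointsH, condition = sc@lightRegime,
                   replicate = rep, partner = "alga",
                   density = noise(at(timepointsH, "algal_cells_ml")),
                   unit = "cells/ml"),
        data.frame(time_h = timepointsH, condition = sc@lightRegime,
                   replicate = rep, partner = "bacterium",
                   density = noise(at(timepointsH, "bacterial_cfu_ml")),
                   unit = "CFU/ml")
      )
    }))
    truth <- do.call(rbind, lapply(seq_len(sipReplicates), function(rep) {
      do.call(rbind, lapply(sipTimepointsH, function(tp) {
        do.call(rbind, lapply(names(cellsPerTimepoint), function(p) {
          k <- cellsPerTimepoint[[p]]
          if (p == "alga") {
            p13 <- at(tp, "algal_f13c"); p15 <- at(tp, "algal_f15n")
            len <- stats::rnorm(k, 6.5, 0.8)  # disk-equivalent diameter, um
          } else {
            p13 <- at(tp, "bacterial_f13c"); p15 <- at(tp, "bacterial_f15n")
            len <- stats::rnorm(k, at(tp, "mean_bacterial_length_um"), 0.15)
          }
          cellNoise <- function(pop, nat, cv = 0.15) {
            exc <- pmax(pop - nat, 0) * exp(stats::rnorm(k, 0, cv))
            pmin(pmax(nat + exc, 0), 1)
          }
          data.frame(
            culture = sprintf("%s_rep%d", sc@lightRegime, rep),
            partner = p, timepoint_h = tp,
            true_p13C = cellNoise(p13, natC),
            true_p15N = cellNoise(p15, natN),
            true_length_um = pmax(len, 0.3)
          )
        }))
      }))
    }))
    truth$cell_id <- sprintf("cell%04d", seq_len(nrow(truth)))
    truth <- truth[c("cell_id", "culture", "partner", "timepoint_h",
                     "true_p13C", "true_p15N", "true_length_um")]
    list(growth = GrowthSeries(obs), ledger = ledger, truth = truth,
         scenario = sc)
  })
}
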