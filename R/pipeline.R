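#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [runFull()]: scenario
#' overrides per light regime, the analysis-field geometry, isotope
#' standards options, the lysate worked-example inputs, bioassay sample
#' concentrations, and the significance level. All randomness derives
#' from the single `seed`, split deterministically per stage.
#'
#' @param seed root integer seed.
#' @return named list; edit fields or pass overrides to [runFull()].
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    alpha = 0.05,
    carbon_convention = "dimer",
    welch = FALSE,
    scenario_overrides = list(),
    sip_timepoints_h = c(12, 24, 36, 48),
    field = list(width_px = 512L, height_px = 512L, pixel_size_um = 0.1,
                 counts_c = 1e5, counts_n = 2e4),
    lysis = list(cfu_in_lysate = 1.7e8, cfu_baseline = 0,
                 lysed_algal_density = 1.6e6,
                 observed_proliferation = 1.1e7,
                 algal_density = 6.1e6,
                 measured_lysis_range_pct = c(1, 3)),
    bioassay_samples_ng_per_l = c(0, 50, 200)
  )
}

#' Validate pipeline input files
#'
#' Checks input files for schema and consistency problems without
#' throwing: every finding is returned as a row with a `level` of
#' `"error"` or `"warning"`. Checks include growth CSV schema and unit
#' labels, image/mask shape agreement, and ion-channel completeness (a
#' missing 32S- channel is only a warning, since it takes no part in the
#' isotope math).
#'
#' @param paths named list; any of `growth_csv`, `image_prefix` (as used
#'   by [readIonImageStack()]), `mask_prefix` (as used by
#'   [readRoiSet()]).
#' @return data.frame with columns `input`, `level`, `message`; zero rows
#'   when everything checks out.
#' @export
validateInputs <- function(paths) {
  findings <- list()
  add <- function(input, level, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      input = input, level = level, message = message)
  stack <- NULL
  if (!is.null(paths$growth_csv)) {
    if (!file.exists(paths$growth_csv)) {
      add("growth_csv", "error", paste0("file not found: ", paths$growth_csv))
    } else {
      g <- try(utils::read.csv(paths$growth_csv), silent = TRUE)
      if (inherits(g, "try-error")) {
        add("growth_csv", "error", "unreadable CSV")
      } else {
        need <- c("time_h", "condition", "replicate", "partner", "density",
                  "unit")
        miss <- setdiff(need, names(g))
        if (length(miss))
          add("growth_csv", "error",
              paste0("missing column(s): ", paste(miss, collapse = ", ")))
        if ("unit" %in% names(g)) {
          bad <- setdiff(unique(g$unit), c("CFU/ml", "cells/ml"))
          if (length(bad))
            add("growth_csv", "error",
                paste0("column 'unit' has unsupported value(s): ",
                       paste(bad, collapse = ", "),
                       " (expected CFU/ml or cells/ml)"))
        }
        if ("density" %in% names(g) && any(!is.finite(g$density) | g$density < 0))
          add("growth_csv", "error", "column 'density' has negative or missing values")
      }
    }
  }
  if (!is.null(paths$image_prefix)) {
    stack <- try(readIonImageStack(paths$image_prefix), silent = TRUE)
    if (inherits(stack, "try-error")) {
      add("image_prefix", "error", "cannot read ion image stack")
      stack <- NULL
    } else {
      missCh <- setdiff(c("C2", "C13C", "CN", "C15N"), channelNames(stack))
      if (length(missCh))
        add("image_prefix", "error",
            paste0("missing channel(s) required for isotope math: ",
                   paste(missCh, collapse = ", ")))
      if (!"S" %in% channelNames(stack))
        add("image_prefix", "warning",
            "missing 32S channel (unused by the isotope math; continuing)")
    }
  }
  if (!is.null(paths$mask_prefix)) {
    rois <- try(readRoiSet(paths$mask_prefix), silent = TRUE)
    if (inherits(rois, "try-error")) {
      add("mask_prefix", "error", "cannot read ROI mask/annotations")
    } else if (!is.null(stack)) {
      dimg <- dim(ionCounts(stack, channelNames(stack)[1]))
      if (!identical(dim(roiMask(rois)), dimg))
        add("mask_prefix", "error",
            sprintf("mask shape (%d x %d) does not match image shape (%d x %d)",
                    nrow(roiMask(rois)), ncol(roiMask(rois)), dimg[1], dimg[2]))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(input = character(), level = character(),
                  message = character())
}

# Internal: simulate, render, and quantify one light regime end to end.
.runRegime <- function(regime, config) {
  sc <- do.call(defaultScenario,
                c(list(lightRegime = regime, seed = config$seed),
                  config$scenario_overrides))
  sim <- simulateCoculture(sc, sipTimepointsH = config$sip_timepoints_h)
  fs <- fieldSpec(widthPx = config$field$width_px,
                  heightPx = config$field$height_px,
                  pixelSizeUm = config$field$pixel_size_um,
                  countsC = config$field$counts_c,
                  countsN = config$field$counts_n)
  groups <- split(sim$truth,
                  list(sim$truth$culture, sim$truth$timepoint_h), drop = TRUE)
  fields <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    g$replicate <- as.integer(sub(".*_rep", "", g$culture))
    renderSipField(g, fs, seed = config$seed + 1000L * i,
                   fieldId = sprintf("%s_f%02d", regime, i))
  })
  std <- IsotopeStandards(carbonConvention = config$carbon_convention)
  quant <- quantifyExperiment(fields, std)
  list(scenario = sc, sim = sim, quant = quant)
}

#' Run the full analysis pipeline on the packaged synthetic bundle
#'
#' Simulates the default coculture under both light regimes, renders and
#' quantifies single-cell ion-image fields, assesses biomass synthesis
#' against CFU doublings, computes the lysis budget worked example, and
#' quantifies a simulated B12 bioassay plate. Writes per-cell CSV, growth
#' CSV, assessment CSV, lysis-budget JSON, bioassay CSV, and a report
#' (JSON plus human-readable text) embedding the seed and config hash.
#'
#' @param config list from [defaultRunConfig()] (edited as needed).
#' @param outDir output directory (created if missing); `NULL` skips all
#'   file output and just returns the report structure.
#' @return invisibly, a list: `report` (headline numbers), `regimes`
#'   (per-regime simulation + quantification), `assessment`, `lysis`,
#'   `bioassay`, `files`.
#' @export
runFull <- function(config = defaultRunConfig(), outDir = NULL) {
  t0 <- Sys.time()
  regimes <- list(
    continuous = .runRegime("continuous", config),
    diurnal_12_12 = .runRegime("diurnal_12_12", config)
  )

  # --- per-regime C_net medians and the cross-regime comparison at 48 h ---
  lastTp <- max(config$sip_timepoints_h)
  bactCnet <- lapply(regimes, function(r) {
    cells <- r$quant$cells
    cells$C_net[cells$partner == "bacterium" &
                  cells$timepoint_h == lastTp & is.finite(cells$C_net)]
  })
  cnetTest <- tTestTwoTailed(bactCnet$continuous, bactCnet$diurnal_12_12,
                             welch = config$welch, alpha = config$alpha)

  # --- expected vs measured N_net and reductive-division flags ---
  assessment <- do.call(rbind, lapply(names(regimes), function(nm) {
    r <- regimes[[nm]]
    g <- growthData(r$sim$growth)
    bact <- g[g$partner == "bacterium", ]
    cells <- r$quant$cells
    med <- stats::aggregate(
      N_net ~ timepoint_h,
      cells[cells$partner == "bacterium", c("timepoint_h", "N_net")],
      stats::median)
    names(med)[2] <- "xnet"
    # assess at growth observations matching the SIP timepoints
    a <- assessSynthesis(bact[bact$time_h %in% med$timepoint_h |
                                bact$time_h == 0, ], med)
    a$condition <- nm
    a
  }))

  # --- density fold and length statistics ---
  bactSeries <- lapply(regimes, function(r) {
    g <- growthData(r$sim$growth)
    GrowthSeries(g[g$partner == "bacterium", ])
  })
  fold <- maxDensityFold(bactSeries$continuous, bactSeries$diurnal_12_12)
  lengths <- do.call(rbind, lapply(names(regimes), function(nm) {
    tr <- regimes[[nm]]$sim$truth
    do.call(rbind, lapply(split(tr[tr$partner == "bacterium", ],
                                tr$timepoint_h[tr$partner == "bacterium"]),
                          function(g) {
      st <- lengthStats(g$true_length_um)
      data.frame(condition = nm, timepoint_h = g$timepoint_h[1],
                 mean_length_um = st$mean, sd_length_um = st$sd, n = st$n)
    }))
  }))
  rownames(lengths) <- NULL
  lenRef <- regimes$continuous$scenario@cellLengthMaxUm
  lenEnd <- lengths$mean_length_um[lengths$condition == "continuous" &
                                     lengths$timepoint_h == lastTp]
  lengthReduction <- percentReduction(lenRef, lenEnd)

  # --- lysis budget worked example ---
  lys <- config$lysis
  budget <- lysisBudget(lys$cfu_in_lysate, lys$cfu_baseline,
                        lys$lysed_algal_density,
                        lys$observed_proliferation, lys$algal_density)
  verdict <- lysisConsistency(budget, lys$measured_lysis_range_pct)

  # --- B12 bioassay ---
  plate <- simulateBioassayPlate(config$bioassay_samples_ng_per_l,
                                 seed = config$seed + 77L)
  bio <- quantifyBioassayPlate(plate)

  report <- list(
    seed = config$seed,
    config_hash = .configHash(config),
    algal_plateau_cells_ml = lapply(regimes, function(r) {
      g <- growthData(r$sim$growth)
      m <- stats::aggregate(density ~ time_h, g[g$partner == "alga", ], mean)
      max(m$density)
    }),
    median_C_net = lapply(bactCnet, stats::median),
    c_net_comparison = list(p_value = cnetTest$p_value,
                            significant = cnetTest$significant,
                            timepoint_h = lastTp),
    max_bacterial_density_fold = fold$fold,
    reductive_division_flagged_by_h = vapply(
      split(assessment, assessment$condition), function(a) {
        fl <- a$timepoint_h[a$reductive_division_flag]
        if (length(fl)) min(fl) else NA_real_
      }, numeric(1)),
    mean_length_final_um = lenEnd,
    length_reduction_pct = lengthReduction,
    lysis_budget = budget[c("yield", "yield_headline",
                            "required_lysed_density",
                            "required_fraction_pct")],
    lysis_verdict = verdict$verdict,
    b12_samples = bio$samples[c("sample_id", "b12_ng_per_l", "censored")],
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  files <- character()
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(obj, name, writer) {
      p <- file.path(outDir, name)
      writer(obj, p)
      files <<- c(files, p)
    }
    allCells <- do.call(rbind, lapply(names(regimes), function(nm) {
      c_ <- regimes[[nm]]$quant$cells
      c_$condition <- nm
      c_
    }))
    w(allCells, "cells.csv", function(o, p) utils::write.csv(o, p, row.names = FALSE))
    allGrowth <- do.call(rbind, lapply(regimes, function(r)
      growthData(r$sim$growth)))
    w(allGrowth, "growth.csv", function(o, p) utils::write.csv(o, p, row.names = FALSE))
    w(assessment, "assessment.csv", function(o, p) utils::write.csv(o, p, row.names = FALSE))
    w(c(budget, verdict["verdict"]), "lysis_budget.json", function(o, p)
      jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
    w(bio$samples, "b12.csv", function(o, p) utils::write.csv(o, p, row.names = FALSE))
    rep2 <- report; rep2$elapsed_s <- NULL  # byte-stable payload
    w(rep2, "report.json", function(o, p)
      jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    txt <- c(
      "Coculture SIP pipeline report",
      sprintf("seed: %d  config: %s", config$seed, report$config_hash),
      sprintf("algal plateau (cells/ml): continuous %.3g, diurnal %.3g",
              report$algal_plateau_cells_ml$continuous,
              report$algal_plateau_cells_ml$diurnal_12_12),
      sprintf("median bacterial C_net at %g h: continuous %.3f, diurnal %.3f (p = %.2g)",
              lastTp, report$median_C_net$continuous,
              report$median_C_net$diurnal_12_12, cnetTest$p_value),
      sprintf("max bacterial density fold (continuous/diurnal): %.2f", fold$fold),
      sprintf("reductive division flagged from %g h (continuous)",
              report$reductive_division_flagged_by_h[["continuous"]]),
      sprintf("lysis budget: %.4g CFU/lysed cell (headline %g); required %.3g cells/ml = %.2f%% of %.3g; %s",
              budget$yield, budget$yield_headline,
              budget$required_lysed_density, budget$required_fraction_pct,
              budget$algal_density, verdict$verdict)
    )
    writeLines(txt, file.path(outDir, "report.txt"))
    files <- c(files, file.path(outDir, "report.txt"))
  }
  invisible(list(report = report, regimes = regimes, assessment = assessment,
                 lysis = c(budget, verdict), bioassay = bio, files = files))
}
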