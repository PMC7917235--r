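#' Default pipeline configuration
#'
#' Flat, per-stage parameter list for the end-to-end density-to-mechanics
#' pipeline. Every stochastic stage has an explicit seed; the resolved
#' configuration is embedded in the pipeline report so every number is
#' traceable.
#'
#' @param ... overrides of the defaults (name = value).
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    # synthetic map (used when no input map path is given)
    synth.length_nm = 100, synth.voxel_nm = 0.925, synth.n_pf = 13L,
    synth.seed = 1L,
    input.map = NULL,
    # preprocessing
    prep.replicate = 1L, prep.solvent_threshold = 0.1,
    prep.total_mass_kgmol = NULL,   # NULL: n_monomers x 55 for synthetic maps
    # coarse-graining
    cg.avg_mass_kgmol = 22, cg.method = "ckcg", cg.seed = 1L,
    # network
    net.cutoff_nm = 6.5, net.A = 1,   # A is rescaled by calibration anyway
    # calibration / force clamp
    clamp.force_nN = 2.36, clamp.target_dL_nm = NULL,  # NULL: from target E
    clamp.target_E_MPa = 100, clamp.area_nm2 = 181.5,
    clamp.terminal_width_nm = 5,
    clamp.force_series_nN = c(1.04, 1.37, 1.70, 2.03, 2.36),
    out.dir = "."
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "PipelineConfig")
}

#' Run the density-to-mechanics pipeline end to end
#'
#' Stages: (synthetic) map generation or MRC input, preprocessing
#' (replication, solvent removal, normalization, mass calibration), CK-CG
#' coarse-graining, MVP-ANM network construction, force-scale calibration
#' against the target Young's modulus via static force-clamp solves, and a
#' force-series modulus check. Writes beads.csv, bonds.csv and report.json
#' into the output directory and returns the report. Deterministic for a
#' fixed configuration.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the report list, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cfg <- config
  for (key in c("synth.seed", "cg.seed"))
    if (is.null(cfg[[key]]) || is.na(cfg[[key]]))
      stop("missing seed in configuration: ", key)
  dir.create(cfg$out.dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(cfg$input.map)) {
    spec <- microtubuleSpec(nProtofilaments = cfg$synth.n_pf,
                            length = cfg$synth.length_nm,
                            voxelSize = cfg$synth.voxel_nm)
    map <- makeMicrotubuleDensity(spec, seed = cfg$synth.seed)
    if (is.null(cfg$prep.total_mass_kgmol))
      cfg$prep.total_mass_kgmol <- nrow(microtubuleLattice(spec)) *
        spec$monomerMass
  } else {
    map <- readDensity(cfg$input.map)
    if (is.null(cfg$prep.total_mass_kgmol))
      stop("prep.total_mass_kgmol is required for external maps")
  }
  map <- replicateAxial(map, cfg$prep.replicate)
  map <- removeSolvent(map, cfg$prep.solvent_threshold)
  map <- normalizeDensity(map)
  map <- calibrateMass(map, cfg$prep.total_mass_kgmol * cfg$prep.replicate)

  beads <- coarseGrain(map, targetAvgMass = cfg$cg.avg_mass_kgmol,
                       method = cfg$cg.method, seed = cfg$cg.seed)
  axisLen <- physicalExtent(map)[symmetryAxis(map)]
  buildAt <- function(A) buildNetwork(beads, cutoff = cfg$net.cutoff_nm, A = A)

  ends <- selectTerminalBeads(beads, axis = symmetryAxis(map),
                              width = cfg$clamp.terminal_width_nm)
  setup <- forceClampSetup(ends$low, ends$high,
                           totalForce = cfg$clamp.force_nN,
                           axis = symmetryAxis(map))
  targetDL <- cfg$clamp.target_dL_nm
  if (is.null(targetDL))
    targetDL <- 1000 * cfg$clamp.force_nN * axisLen /
      (cfg$clamp.area_nm2 * cfg$clamp.target_E_MPa)
  cal <- calibrateForceScale(buildAt, setup, targetDL,
                             candidateAs = cfg$net.A * c(0.25, 1, 4))
  model <- buildAt(cal$A)

  disp <- numeric(length(cfg$clamp.force_series_nN))
  Xprev <- NULL   # continuation along the force series
  for (k in seq_along(disp)) {
    s <- forceClampSetup(ends$low, ends$high,
                         totalForce = cfg$clamp.force_series_nN[k],
                         axis = symmetryAxis(map))
    Xprev <- minimizeUnderForce(model, s, start = Xprev)
    disp[k] <- measureDisplacement(Xprev, s, beadPositions(beads))
  }
  series <- youngsModulusFromSeries(cfg$clamp.force_series_nN, disp,
                                    length0 = axisLen,
                                    area = cfg$clamp.area_nm2)

  beadsCsv <- file.path(cfg$out.dir, "beads.csv")
  write.csv(data.frame(id = seq_len(nrow(beadPositions(beads))),
                       x_nm = beadPositions(beads)[, 1],
                       y_nm = beadPositions(beads)[, 2],
                       z_nm = beadPositions(beads)[, 3],
                       mass_kg_per_mol = beadMasses(beads)),
            beadsCsv, row.names = FALSE)
  write.csv(bondTable(model), file.path(cfg$out.dir, "bonds.csv"),
            row.names = FALSE)

  report <- list(
    config = unclass(cfg),
    map = list(extent_nm = as.numeric(physicalExtent(map)),
               retained_voxels = sum(retainedMask(map)),
               total_mass_kgmol = massScale(map) *
                 sum(densityValues(map)[retainedMask(map)])),
    beads = list(n = nrow(beadPositions(beads)),
                 mean_mass_kgmol = mean(beadMasses(beads)),
                 objective = beads@objective,
                 iterations = beads@nIterations),
    network = list(n_bonds = nrow(bondTable(model)),
                   cutoff_nm = model@cutoff, R_nm = model@R,
                   A = model@A),
    mechanics = list(target_displacement_nm = targetDL,
                     calibrated_displacement_nm = cal$displacement,
                     force_series_nN = cfg$clamp.force_series_nN,
                     displacements_nm = disp,
                     youngs_modulus_MPa = series$E,
                     r_squared = series$r.squared)
  )
  jsonlite::write_json(report, file.path(cfg$out.dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
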