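#' @include synthetic.R
NULL

.GENETICS_KEYS <- c("fasta", "popmap", "fixture", "seed", "h11Parent",
                    "primers", "geneticCode", "confidence", "outDir")
.HINDCAST_KEYS <- c("grid", "responseFunction", "lgm", "depthBand",
                    "binWidth", "latRange", "seed", "outDir")

# load a config from a YAML path or pass a list through; reject unknown keys
.loadConfig <- function(config, known, stage) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown ", stage, " config key(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(config$outDir)) stop("config must set outDir")
  config
}

.manifest <- function(outDir, inputs, extra) {
  files <- list.files(outDir, full.names = TRUE)
  files <- files[basename(files) != "run_manifest.json"]
  man <- c(list(inputs = inputs,
                outputs = lapply(stats::setNames(files, basename(files)),
                                 function(f) unname(tools::md5sum(f)))),
           extra)
  jsonlite::write_json(man, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  man
}

#' Run the haplotype-genetics stage end to end
#'
#' Reads (or generates) an aligned COI dataset, optionally trims primers,
#' runs the translation QC, applies the complete-deletion site filter,
#' collapses haplotypes, computes the diversity report and builds and
#' exports the statistical-parsimony network. All artifacts land in
#' `outDir`; identical config + seed give byte-identical TSV/JSON outputs.
#'
#' Config keys (list or YAML path): `fasta` + `popmap` paths, or
#' `fixture: true` with optional `seed` / `h11Parent` to use the built-in
#' study fixture; `primers` (`true` for the built-in Gaz F2/R2 pair, or a
#' list `forward`/`reverse`/`maxMismatch`); `geneticCode` (default `"1"`);
#' `confidence` (default 0.95); `outDir` (required).
#'
#' @param config List or YAML file path.
#' @return Invisibly, a list with the intermediate objects (`seqs`, `qc`,
#'   `table`, `report`, `limit`, `network`, `manifest`).
#' @export
runGenetics <- function(config) {
  cfg <- .loadConfig(config, .GENETICS_KEYS, "genetics")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)

  if (isTRUE(cfg$fixture)) {
    fx <- makePaperFixture(
      seed = seed,
      h11Parent = if (is.null(cfg$h11Parent)) "H10" else cfg$h11Parent,
      withPrimers = !is.null(cfg$primers) && !isFALSE(cfg$primers))
    seqs <- fx$seqs
    partition <- fx$partition
    inputs <- list(fixture = TRUE, seed = seed)
  } else {
    if (is.null(cfg$fasta)) stop("config must set fasta or fixture: true")
    if (is.null(cfg$popmap)) stop("config must set popmap")
    seqs <- readAlignedFasta(cfg$fasta)
    partition <- readPopulationMap(cfg$popmap)
    inputs <- list(fasta = cfg$fasta, popmap = cfg$popmap)
  }

  trimmedCols <- integer(0)
  if (!is.null(cfg$primers) && !isFALSE(cfg$primers)) {
    pr <- if (isTRUE(cfg$primers)) as.list(coiPrimers()) else cfg$primers
    mm <- if (is.null(pr$maxMismatch)) 1L else pr$maxMismatch
    tr <- trimPrimers(seqs, pr$forward, pr$reverse, maxMismatch = mm)
    seqs <- tr$seqs
    trimmedCols <- tr$trimmedColumns
    utils::write.table(tr$log, file.path(cfg$outDir, "trim_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  qc <- translationQc(seqs, geneticCode = if (is.null(cfg$geneticCode)) "1"
                      else cfg$geneticCode)
  utils::write.table(qc, file.path(cfg$outDir, "translation_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (any(!qc$passed))
    warning(sum(!qc$passed), " sequence(s) failed translation QC")

  writeAlignedFasta(seqs, file.path(cfg$outDir, "alignment_trimmed.fasta"))
  writeNexus(seqs, file.path(cfg$outDir, "alignment.nex"))

  cd <- completeDeletion(seqs)
  table <- collapseHaplotypes(cd$seqs, partition)
  writeHaplotypeTable(table, file.path(cfg$outDir, "haplotypes"))

  report <- diversityReport(table)
  formatDiversityReport(report,
                        file.path(cfg$outDir, "diversity_report.tsv"))

  conf <- if (is.null(cfg$confidence)) 0.95 else cfg$confidence
  limit <- connectionLimit(sitesUsed(table), confidence = conf)
  net <- buildNetwork(table, limit)
  exportNetwork(net, file.path(cfg$outDir, "network.graphml"), "graphml")
  exportNetwork(net, file.path(cfg$outDir, "network_edges.tsv"),
                "tsv-edgelist")

  manifest <- .manifest(cfg$outDir, inputs, list(
    n_sequences = length(seqs), L = seqLength(seqs),
    trimmed_columns = length(trimmedCols),
    L_used = sitesUsed(table), sites_excluded = cd$filter$n_excluded,
    connection_limit = limit@limit, confidence = conf,
    qc_failures = sum(!qc$passed)))
  invisible(list(seqs = seqs, qc = qc, table = table, report = report,
                 limit = limit, network = net, manifest = manifest))
}

#' Run the glacial-hindcast stage end to end
#'
#' Builds (or reads) present-day and LGM scenario grids, predicts cover
#' through the thermal response curve, masks by depth band under each
#' scenario's sea level, computes latitudinal profiles and the equatorward
#' range shift, and writes every artifact to `outDir`.
#'
#' Config keys: `grid` (either `sst`/`bathymetry` TSV paths or [gridSpec()]
#' parameters for the synthetic generator), `responseFunction`
#' (`tOpt`/`tMax`/`peakCover`), `lgm` (`seaLevelOffset`, default 120;
#' `cooling`, default 4), `depthBand` (default 0--80 m), `binWidth`
#' (default 0.5), `latRange`, `seed`, `outDir` (required).
#'
#' @param config List or YAML file path.
#' @return Invisibly, a list with `present` and `lgm` prediction lists,
#'   their `profiles`, the `shift` summary and the `manifest`.
#' @export
runHindcast <- function(config) {
  cfg <- .loadConfig(config, .HINDCAST_KEYS, "hindcast")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  lgmPar <- cfg$lgm
  offset <- if (is.null(lgmPar$seaLevelOffset)) 120 else lgmPar$seaLevelOffset
  cooling <- if (is.null(lgmPar$cooling)) 4 else lgmPar$cooling
  band <- if (is.null(cfg$depthBand)) c(0, 80) else as.numeric(cfg$depthBand)
  if (length(band) != 2L || band[1L] >= band[2L])
    stop("depthBand must be (min, max) with min < max")
  binW <- if (is.null(cfg$binWidth)) 0.5 else cfg$binWidth

  gp <- cfg$grid
  if (!is.null(gp$sst) && !is.null(gp$bathymetry)) {
    sstIn <- readGridTsv(gp$sst)
    batIn <- readGridTsv(gp$bathymetry)
    if (!identical(dim(sstIn$grid), dim(batIn$grid)))
      stop("sst and bathymetry rasters are not co-registered")
    gPres <- list(sst = sstIn$grid, bathymetry = batIn$grid,
                  lat = sstIn$lat, lon = sstIn$lon)
    gLgm <- gPres
    gLgm$sst <- gLgm$sst - cooling
    inputs <- list(sst = gp$sst, bathymetry = gp$bathymetry)
  } else {
    args <- gp[setdiff(names(gp), c("sst", "bathymetry"))]
    baseSpec <- do.call(gridSpec, c(args, list(seed = seed)))
    gPres <- simulateGrids(baseSpec)
    lgmSpec <- baseSpec
    lgmSpec$cooling <- baseSpec$cooling + cooling
    gLgm <- simulateGrids(lgmSpec)
    inputs <- list(gridSpec = args, seed = seed)
  }
  latRange <- if (is.null(cfg$latRange)) c(-38, -18)
              else as.numeric(cfg$latRange)

  rfPar <- cfg$responseFunction
  rf <- responseFunction(
    tOpt = if (is.null(rfPar$tOpt)) 23 else rfPar$tOpt,
    tMax = if (is.null(rfPar$tMax)) 26 else rfPar$tMax,
    peakCover = if (is.null(rfPar$peakCover)) 60 else rfPar$peakCover)

  scnPres <- coverScenario(gPres$sst, gPres$bathymetry, gPres$lat, gPres$lon,
                           seaLevelOffset = 0, depthBand = band,
                           latRange = latRange)
  scnLgm <- coverScenario(gLgm$sst, gLgm$bathymetry, gLgm$lat, gLgm$lon,
                          seaLevelOffset = offset, depthBand = band,
                          latRange = latRange)
  present <- predictCoverGrid(scnPres, rf)
  lgm <- predictCoverGrid(scnLgm, rf)

  profPres <- latitudinalProfile(present$cover, present$mask, gPres$lat,
                                 binWidth = binW, latRange = latRange)
  profLgm <- latitudinalProfile(lgm$cover, lgm$mask, gLgm$lat,
                                binWidth = binW, latRange = latRange)

  writeGridTsv(present$cover, gPres$lat, gPres$lon,
               file.path(cfg$outDir, "cover_present.tsv"))
  writeGridTsv(lgm$cover, gLgm$lat, gLgm$lon,
               file.path(cfg$outDir, "cover_lgm.tsv"))
  utils::write.table(profPres, file.path(cfg$outDir, "profile_present.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(profLgm, file.path(cfg$outDir, "profile_lgm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  shift <- list(
    peak_shift_deg = rangeShift(profPres, profLgm, "peak"),
    centroid_shift_deg = rangeShift(profPres, profLgm, "centroid"),
    sea_level_offset_m = offset, cooling_degC = cooling)
  jsonlite::write_json(shift, file.path(cfg$outDir, "shift_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest <- .manifest(cfg$outDir, inputs, list(
    depth_band_m = band, bin_width_deg = binW, lat_range = latRange,
    response = list(tOpt = rf@tOpt, tMax = rf@tMax,
                    peakCover = rf@peakCover)))
  invisible(list(present = present, lgm = lgm,
                 profiles = list(present = profPres, lgm = profLgm),
                 shift = shift, manifest = manifest))
}
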