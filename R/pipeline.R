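## Orchestration of the pulling-study experiment suites: simulate under a
## protocol preset, analyze a run directory, extract constant-force
## kinetics, and run Bell parameter-recovery experiments. All stages are
## driven by one structured config (YAML or list) with explicit seeds.

.requiredConfigFields <- c("seed", "out")

#' Read and validate a run configuration
#'
#' @param config path to a YAML file, or a list. Recognised top-level
#'   fields: `model` (overrides for [bentModelConfig()]), `protocol`
#'   (`preset` one of `equilibrate`, `cv_pull`, `cf_pull`,
#'   `free_from_snapshot`, plus preset fields), `params` (fields of
#'   [simParams()]), `analysis` (`sasaPoints`, `stride`), `seed`, `out`.
#' @return validated config list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  miss <- setdiff(.requiredConfigFields, names(config))
  if (length(miss) > 0)
    stop("config misses required field(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(config$seed))
    stop("config: every stochastic stage needs an explicit integer seed")
  preset <- config$protocol$preset
  if (!is.null(preset) &&
      !preset %in% c("equilibrate", "cv_pull", "cf_pull",
                     "free_from_snapshot"))
    stop("config: unknown protocol preset '", preset, "'")
  if (identical(preset, "cf_pull") && is.null(config$protocol$forces))
    stop("config: cf_pull preset needs a 'forces' vector")
  config
}

.configHash <- function(config) {
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  h
}

.simParamsFromConfig <- function(config, seed) {
  p <- config$params
  if (is.null(p)) p <- list()
  args <- p[intersect(names(p), c("temperature", "gamma", "dt",
                                  "duration", "saveStride"))]
  if (!is.null(args$saveStride)) args$saveStride <- as.integer(args$saveStride)
  args$seed <- as.integer(seed)
  do.call(simParams, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeRunDir <- function(dir, built, run, label) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writePDB(built$model, file.path(dir, "model.pdb"))
  writeAnnotations(built$model, file.path(dir, "annotations.csv"))
  write.csv(built$topology@bonds, file.path(dir, "bonds.csv"),
            row.names = FALSE)
  write.csv(built$topology@hinges, file.path(dir, "hinges_topology.csv"),
            row.names = FALSE)
  write.csv(built$topology@contacts, file.path(dir, "contacts.csv"),
            row.names = FALSE)
  writeTrajectoryCSV(run$trajectory, file.path(dir, "trajectory.csv"))
  write.csv(run$forceRecord, file.path(dir, "forces.csv"),
            row.names = FALSE)
  c("model.pdb", "annotations.csv", "bonds.csv", "hinges_topology.csv",
    "contacts.csv", "trajectory.csv", "forces.csv")
}

#' Build the model and run the configured pulling protocol(s)
#'
#' The `cf_pull` preset performs one run per configured force (seeds
#' `seed, seed+1, ...`); other presets perform a single run. Each run
#' directory receives the structure (PDB + sidecar annotations), topology
#' tables, the trajectory and the force record; a log records the seed and
#' config hash so any output can be re-derived bit-identically.
#'
#' @param config from [readRunConfig()].
#' @param built optional pre-built model list (from [buildBentModel()]);
#'   by default the model is built from `config$model`.
#' @param startCoords optional starting coordinates (snapshot restarts).
#' @return manifest list: `runDirs`, `files` per run, `seeds`, `configHash`.
#' @export
cmdSimulate <- function(config, built = NULL, startCoords = NULL) {
  config <- readRunConfig(config)
  if (is.null(built))
    built <- buildBentModel(utils::modifyList(bentModelConfig(),
                                              config$model %||% list()))
  pc <- config$protocol %||% list(preset = "equilibrate")
  preset <- pc$preset %||% "equilibrate"
  pull <- list(composite = pc$pull %||% "pull_head")
  cons <- list(composite = pc$constraint %||% "constraint_tail")
  mkProtocol <- function(force = 0) {
    switch(preset,
      equilibrate = ,
      free_from_snapshot = pullingProtocol("free", pull, cons,
                                           kConstraintKcal =
                                             pc$kConstraintKcal %||% 10),
      cv_pull = pullingProtocol("constant-velocity", pull, cons,
                                kKcal = pc$kKcal %||% 0.5,
                                v = pc$v %||% 1,
                                direction = pc$direction %||% "fixed",
                                kConstraintKcal = pc$kConstraintKcal %||% 10),
      cf_pull = pullingProtocol("constant-force", pull, cons,
                                force = force,
                                direction = pc$direction %||% "fixed",
                                kConstraintKcal = pc$kConstraintKcal %||% 10))
  }
  forces <- if (preset == "cf_pull") pc$forces else 0
  runDirs <- character(0); files <- list(); seeds <- integer(0)
  for (i in seq_along(forces)) {
    seed <- as.integer(config$seed) + (i - 1L)
    params <- .simParamsFromConfig(config, seed)
    proto <- mkProtocol(forces[i])
    run <- runDynamics(built$model, built$topology, proto, params,
                       map = built$map, startCoords = startCoords)
    dir <- if (length(forces) > 1)
      file.path(config$out, sprintf("force_%g", forces[i]))
    else config$out
    fl <- .writeRunDir(dir, built, run, preset)
    log <- c(sprintf("preset: %s", preset),
             sprintf("seed: %d", seed),
             sprintf("force_pN: %g", forces[i]),
             sprintf("config_hash: %s", .configHash(config)),
             sprintf("package_version: %s",
                     as.character(utils::packageVersion("pullMD"))))
    writeLines(log, file.path(dir, "run_log.txt"))
    runDirs <- c(runDirs, dir)
    files[[dir]] <- fl
    seeds <- c(seeds, seed)
  }
  list(runDirs = runDirs, files = files, seeds = seeds,
       configHash = .configHash(config), built = built)
}

#' The shipped stability-metric specifications
#'
#' COM-distance metrics mirroring the interface and stability analyses of
#' pulling studies: the hybrid/betaTD salt-bridge analog, the hybrid/EGF4
#' hydrophobic-cluster distance, the thigh-sidechain-to-genu-ion
#' coordination (event: below 4 A held 1 ns), and the ligand-to-MIDAS
#' distance (resolves empty on the unliganded synthetic model and is then
#' skipped).
#'
#' @return named list of [distanceMetricSpec()] lists.
#' @export
standardMetricSpecs <- function() {
  list(
    salt_bridge_D393_R633 = distanceMetricSpec(
      "salt_bridge_D393_R633", list(composite = "salt_bridge_A"),
      list(composite = "salt_bridge_B")),
    hydrophobic_cluster = distanceMetricSpec(
      "hydrophobic_cluster", list(composite = "hydrophobic_A"),
      list(composite = "hydrophobic_B")),
    genu_ion_D457 = distanceMetricSpec(
      "genu_ion_D457", list(composite = "genu_A"),
      list(composite = "genu_B"), threshold = 4, direction = "below",
      holdTime = 1),
    ligand_asp_midas = distanceMetricSpec(
      "ligand_asp_midas", list(composite = "ligand_asp"),
      list(composite = "midas"), threshold = 3, direction = "below",
      holdTime = 1))
}

#' Analyze a simulation run directory
#'
#' Emits the trajectory analyses: extension and RMSD series, the
#' force-extension curve with detected peaks, per-domain buried surface
#' areas between headpiece and tailpiece, interface hydrogen-bond counts,
#' knee hinge angles, and the named COM-distance metrics.
#'
#' @param config from [readRunConfig()] (its `analysis` block sets
#'   `sasaPoints`, default 240, and the frame `stride`, default 1).
#' @param runDir directory written by [cmdSimulate()].
#' @param built the model list the run used (rebuilt from config when NULL).
#' @return named list of data.frames (also written as CSVs to `runDir`).
#' @export
cmdAnalyze <- function(config, runDir, built = NULL) {
  config <- readRunConfig(config)
  trajFile <- file.path(runDir, "trajectory.csv")
  if (!file.exists(trajFile))
    stop("cmdAnalyze: missing expected file ", trajFile)
  if (is.null(built))
    built <- buildBentModel(utils::modifyList(bentModelConfig(),
                                              config$model %||% list()))
  model <- built$model; map <- built$map
  traj <- readTrajectoryCSV(trajFile, model)
  forces <- read.csv(file.path(runDir, "forces.csv"))
  an <- config$analysis %||% list()
  params <- sasaParams(nPoints = as.integer(an$sasaPoints %||% 240L))
  stride <- as.integer(an$stride %||% 1L)

  pullSel <- resolveSelection(model, map, list(composite = "pull_head"))
  consSel <- resolveSelection(model, map,
                              list(composite = "constraint_tail"))
  head <- resolveSelection(model, map, list(composite = "headpiece"))
  tail <- resolveSelection(model, map, list(composite = "tailpiece"))
  domSel <- function(d, ch) resolveSelection(model, map,
                                             list(chain = ch, domains = d))
  hybrid <- domSel("hybrid", "B"); btd <- domSel("betaTD", "B")
  egf4 <- domSel("EGF4", "B")

  out <- list()
  out$extension <- extensionSeries(traj, pullSel, consSel)
  out$rmsd <- rmsdSeries(traj, 1L, serials = model@atoms$serial)
  fe <- data.frame(extension_A = out$extension$extension_A,
                   force_pN = forces$force_pN)
  fe <- fe[order(fe$extension_A), ]
  out$force_extension <- fe
  out$peaks <- tryCatch(
    detectForcePeaks(fe$extension_A, fe$force_pN,
                     smoothWindow = an$smoothWindow %||% 2,
                     minProminence = an$minProminence %||% 0),
    error = function(e) data.frame(extension_A = numeric(0),
                                   force_pN = numeric(0),
                                   prominence_pN = numeric(0)))
  out$buried_sasa <- buriedSasaSeries(
    traj, head, tail,
    domains = list(hybrid = hybrid, betaTD = btd, EGF4 = egf4),
    params = params, stride = stride)
  out$hbonds_hybrid_betaTD <- hbondCountSeries(traj, hybrid, btd,
                                               stride = stride)
  pairs <- list(
    hingePair("thigh/calf1", domSel("thigh", "A"), domSel("calf1", "A")),
    hingePair("EGF1/EGF2", domSel("EGF1", "B"), domSel("EGF2", "B")),
    hingePair("EGF2/EGF3", domSel("EGF2", "B"), domSel("EGF3", "B")))
  out$hinge_angles <- hingeAngleSeries(traj, pairs)
  metrics <- list()
  for (ms in standardMetricSpecs()) {
    A <- tryCatch(resolveSelection(model, map, ms$A),
                  error = function(e) integer(0))
    B <- tryCatch(resolveSelection(model, map, ms$B),
                  error = function(e) integer(0))
    if (length(A) == 0 || length(B) == 0) next
    metrics[[ms$name]] <- comDistanceSeries(traj, A, B, name = ms$name)
  }
  out$distances <- if (length(metrics) > 0) do.call(rbind, metrics)
    else data.frame(time_ns = numeric(0), distance_A = numeric(0),
                    metric = character(0))
  for (nm in names(out))
    write.csv(out[[nm]], file.path(runDir, paste0(nm, ".csv")),
              row.names = FALSE)
  out
}

#' Constant-force kinetics across run directories
#'
#' Extracts the unbending waiting time of each constant-force run from its
#' extension trace and fits the Bell model to (force, waiting time).
#'
#' @param config from [readRunConfig()] (block `kinetics`: `delta`,
#'   `baselineWindow`, `holdTime` of [waitingTimeRule()]).
#' @param runDirs constant-force run directories (from the `cf_pull`
#'   preset); order does not matter.
#' @param built model list (rebuilt from config when NULL).
#' @return list `waitingTimes` (data.frame `force_pN, time_ns, runDir`) and
#'   `fit` (a [BellFitResult-class]).
#' @export
cmdKinetics <- function(config, runDirs, built = NULL) {
  config <- readRunConfig(config)
  if (is.null(built))
    built <- buildBentModel(utils::modifyList(bentModelConfig(),
                                              config$model %||% list()))
  kc <- config$kinetics %||% list()
  rule <- waitingTimeRule(baselineWindow = kc$baselineWindow %||% 1,
                          delta = kc$delta %||% 20,
                          holdTime = kc$holdTime %||% 1)
  model <- built$model; map <- built$map
  pullSel <- resolveSelection(model, map, list(composite = "pull_head"))
  consSel <- resolveSelection(model, map,
                              list(composite = "constraint_tail"))
  rows <- list()
  for (dir in runDirs) {
    traj <- readTrajectoryCSV(file.path(dir, "trajectory.csv"), model)
    forces <- read.csv(file.path(dir, "forces.csv"))
    ext <- extensionSeries(traj, pullSel, consSel)
    wt <- detectWaitingTime(ext, rule)
    rows[[length(rows) + 1L]] <-
      data.frame(force_pN = forces$force_pN[nrow(forces)],
                 time_ns = wt, runDir = dir)
  }
  wt <- do.call(rbind, rows)
  good <- wt[!is.na(wt$time_ns), , drop = FALSE]
  if (nrow(good) < 2)
    stop("cmdKinetics: fewer than 2 detected transitions; ",
         "use longer runs or higher forces")
  fit <- fitBell(good$force_pN, good$time_ns,
                 temperature = config$params$temperature %||% 300)
  list(waitingTimes = wt, fit = fit)
}

#' Bell parameter-recovery experiment
#'
#' Draws synthetic escape data from known (t0, dx) on a force grid with
#' [simulateEscape()] and refits with [fitBell()], `replicates` times.
#' Fitting uses `ln(mean waiting time)` per force: the mean of an
#' exponential sample is an unbiased estimate of tau(F), whereas a single
#' drawn `ln t` per force underestimates `ln tau` by the Euler-Mascheroni
#' constant and would bias t0 low.
#'
#' @param config list (or YAML path) with block `recover`: `t0` (ns), `dx`
#'   (A), `forces` (pN), `samplesPerForce`, `replicates`; plus `seed`.
#' @return list `fits` (data.frame `t0_ns, dx_A` per replicate), `median`
#'   (named vector), `truth`.
#' @export
cmdRecover <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  rc <- config$recover %||% list()
  t0 <- rc$t0 %||% 728
  dx <- rc$dx %||% 1.2
  forces <- rc$forces %||% c(97, 122, 146, 170, 195)
  m <- rc$samplesPerForce %||% 100L
  R <- rc$replicates %||% 200L
  temp <- rc$temperature %||% 300
  if (t0 <= 0 || dx < 0) stop("cmdRecover: invalid truth parameters")
  seed <- as.integer(config$seed %||% 1L)
  fits <- bellRecoveryExperiment(t0, dx, forces, temp, m, R, seed)
  list(fits = fits,
       median = c(t0_ns = median(fits$t0_ns), dx_A = median(fits$dx_A)),
       truth = c(t0_ns = t0, dx_A = dx))
}

#' Replicated escape-simulation + Bell-refit experiment
#'
#' One replicate: draw `samplesPerForce` exponential waiting times at each
#' force, average them per force, and fit `ln(mean t)` vs `F` by OLS.
#'
#' @param t0,dx truth parameters (ns, A).
#' @param forces force grid, pN.
#' @param temperature K.
#' @param samplesPerForce draws per force.
#' @param replicates number of replicate fits.
#' @param seed base seed; replicate r uses `seed + r - 1`.
#' @return data.frame `replicate, t0_ns, dx_A`.
#' @export
bellRecoveryExperiment <- function(t0, dx, forces, temperature = 300,
                                   samplesPerForce = 100L,
                                   replicates = 200L, seed = 1L) {
  out <- data.frame(replicate = seq_len(replicates), t0_ns = NA_real_,
                    dx_A = NA_real_)
  for (r in seq_len(replicates)) {
    sim <- simulateEscape(t0, dx, forces, temperature,
                          samplesPerForce, seed = seed + r - 1L)
    means <- tapply(sim$time_ns, sim$force_pN, mean)
    f <- as.numeric(names(means))
    fit <- fitBell(f, as.numeric(means), temperature)
    out$t0_ns[r] <- fit@t0
    out$dx_A[r] <- fit@dx
  }
  out
}
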