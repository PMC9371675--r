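# Configuration files, tabular output and the high-level entry points
# used by the command-line wrapper (inst/scripts/multiplexdrive.R).
#
# A run configuration is one YAML file with up to three blocks:
#   params: arguments of driveParams()
#   theory: arguments of theoryConstants()
#   run:    NGrid, nReps, baseSeed, outputDir, trajectories
# Unknown keys anywhere are rejected so experiment definitions stay
# reviewable and diffable.

.RUN_KEYS <- c("NGrid", "nReps", "baseSeed", "outputDir", "trajectories")

#' Read and validate a run configuration
#'
#' @param path path to a YAML configuration file.
#' @return list with elements `params` ([DriveParams-class]), `consts`
#'   ([TheoryConstants-class]) and `run` (list of run controls with
#'   defaults `nReps = 500`, `baseSeed = 1`, `trajectories = FALSE`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  bad <- setdiff(names(cfg), c("params", "theory", "run"))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))

  pArgs <- cfg$params
  if (is.null(pArgs)) pArgs <- list()
  badP <- setdiff(names(pArgs), names(formals(driveParams)))
  if (length(badP))
    stop("unknown params key(s): ", paste(badP, collapse = ", "))
  if (!all(c("m", "K") %in% names(pArgs)))
    stop("config params block must provide the required keys m and K")
  params <- do.call(driveParams, pArgs)

  tArgs <- cfg$theory
  if (is.null(tArgs)) tArgs <- list()
  badT <- setdiff(names(tArgs), names(formals(theoryConstants)))
  if (length(badT))
    stop("unknown theory key(s): ", paste(badT, collapse = ", "))
  if (!is.null(tArgs$gammaM)) tArgs$gammaM <- unlist(tArgs$gammaM)
  consts <- do.call(theoryConstants, tArgs)

  run <- cfg$run
  if (is.null(run)) run <- list()
  badR <- setdiff(names(run), .RUN_KEYS)
  if (length(badR))
    stop("unknown run key(s): ", paste(badR, collapse = ", "))
  if (is.null(run$NGrid)) run$NGrid <- params@K
  run$NGrid <- as.numeric(unlist(run$NGrid))
  if (is.null(run$nReps)) run$nReps <- 500L
  if (is.null(run$baseSeed)) run$baseSeed <- 1L
  if (is.null(run$trajectories)) run$trajectories <- FALSE

  list(params = params, consts = consts, run = run)
}

#' Run a replicate batch from a configuration file
#'
#' Executes [resistanceProbability()] over the configured N grid and
#' writes, under the output directory: `outcomes.csv` (one row per
#' replicate with labelled haplotype-frequency columns), `summary.csv`
#' and `summary.json` (per-N resistance fraction with binomial CI), and
#' `manifest.json` (configuration echo, seeds and package version, enough
#' to re-run the batch exactly).
#'
#' @param config path to a YAML configuration, or the list returned by
#'   [readRunConfig()].
#' @param outputDir output directory (created if missing); defaults to
#'   the config's `run$outputDir`.
#' @return invisibly, the per-N summary data.frame.
#' @export
cliSimulate <- function(config, outputDir = NULL) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  outputDir <- if (!is.null(outputDir)) outputDir else cfg$run$outputDir
  if (is.null(outputDir)) stop("no output directory given")
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outputDir))
    stop("cannot create output directory: ", outputDir)

  summ <- resistanceProbability(cfg$params, cfg$run$NGrid,
                                nReps = cfg$run$nReps,
                                baseSeed = cfg$run$baseSeed)
  outcomes <- attr(summ, "outcomes")
  utils::write.csv(outcomes, file.path(outputDir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(summ, file.path(outputDir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summ, file.path(outputDir, "summary.json"),
                       dataframe = "rows", digits = NA)
  manifest <- list(
    package = "multiplexdrive",
    version = as.character(utils::packageVersion("multiplexdrive")),
    rVersion = R.version.string,
    baseSeed = cfg$run$baseSeed,
    NGrid = cfg$run$NGrid,
    nReps = cfg$run$nReps,
    params = .paramsAsList(cfg$params),
    theory = .constsAsList(cfg$consts))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summ)
}

#' Theory report over a parameter grid
#'
#' Evaluates the analytic layer on the cross product of the requested
#' gRNA numbers and fitness costs: critical population sizes for each
#' mechanism and combined, the `p = 0.05` contour, minimal gRNA numbers
#' (closed form and brute force), and the standing-variation
#' amplification ratio.
#'
#' @param params a [DriveParams-class] object (template; `m` and `sigma`
#'   are swept).
#' @param consts a [TheoryConstants-class] object.
#' @param mGrid integer vector of gRNA numbers; default 1:3.
#' @param sigmaGrid numeric vector of fitness costs; default the
#'   template's sigma.
#' @param p contour probability; default 0.05.
#' @param outputDir optional directory; writes `theory.csv` when given.
#' @return data.frame with one row per (m, sigma) combination.
#' @export
cliTheory <- function(params, consts = theoryConstants(), mGrid = 1:3,
                      sigmaGrid = params@sigma, p = 0.05,
                      outputDir = NULL) {
  grid <- expand.grid(m = mGrid, sigma = sigmaGrid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    pm <- params
    pm@m <- as.integer(grid$m[g])
    pm@sigma <- grid$sigma[g]
    NN <- criticalNNhej(pm, consts)
    ND <- criticalNDenovo(pm, consts)
    NS <- criticalNStanding(pm, consts)
    NC <- criticalNCombined(pm, consts)
    data.frame(
      m = pm@m, sigma = pm@sigma, beta = pm@beta, xi = pm@xi,
      NStarNhej = NN, NStarDenovo = ND, NStarStanding = NS,
      NStarCombined = NC, contourN = contourN(p, NC),
      minGuidesNhej = as.integer(minGuidesNhej(pm@K, p, pm, consts)),
      minGuidesStanding = as.integer(minGuidesStanding(pm@K, p, pm,
                                                       consts)),
      amplification = amplificationRatio(pm@m, pm@sigma, consts))
  })
  out <- do.call(rbind, rows)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(outputDir, "theory.csv"),
                     row.names = FALSE)
  }
  out
}

#' Fit the resistance sigmoid to an outcomes file
#'
#' Reads a per-replicate outcomes CSV in the schema written by
#' [cliSimulate()], aggregates resistance counts by N, and fits
#' `p = 1 - exp(-N / N*)` by binomial maximum likelihood. When `params`
#' is supplied the implied mechanism constants are reported as well.
#'
#' @param csvPath path to an `outcomes.csv` file.
#' @param params optional [DriveParams-class] for implied-constant
#'   reporting.
#' @param jsonPath optional path; the fit is written there as JSON.
#' @return list with `NStar`, `ci`, `logLik`, `boundary` and (with
#'   `params`) `impliedGammaN` / `impliedGammaM`.
#' @export
cliFit <- function(csvPath, params = NULL, jsonPath = NULL) {
  if (!file.exists(csvPath)) stop("outcomes file not found: ", csvPath)
  outcomes <- tryCatch(
    utils::read.csv(csvPath, stringsAsFactors = FALSE),
    error = function(e) stop("malformed outcomes CSV: ",
                             conditionMessage(e)))
  if (nrow(outcomes) == 0L) stop("no data: the outcomes CSV is empty")
  need <- c("N", "outcome")
  if (!all(need %in% names(outcomes)))
    stop("outcomes CSV must have columns N and outcome")
  agg <- stats::aggregate(outcome ~ N, data = outcomes,
                          FUN = function(o) sum(o == "resistance"))
  names(agg)[2] <- "nResistance"
  agg$nReps <- as.vector(table(outcomes$N)[as.character(agg$N)])
  fit <- fitSigmoid(agg)
  out <- list(NStar = fit@NStar, ci = fit@ci, logLik = fit@logLik,
              boundary = fit@boundary)
  if (!is.null(params)) {
    out$impliedGammaN <- impliedGamma(fit, params, "nhej")
    out$impliedGammaM <- impliedGamma(fit, params, "denovo")
  }
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA)
  out
}

.paramsAsList <- function(p) {
  nm <- slotNames(p)
  out <- lapply(nm, function(s) slot(p, s))
  names(out) <- nm
  out
}

.constsAsList <- function(x) {
  nm <- slotNames(x)
  out <- lapply(nm, function(s) slot(x, s))
  names(out) <- nm
  out
}
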