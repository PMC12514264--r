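.logLevel <- new.env(parent = emptyenv())
.logLevel$value <- "info"

.log <- function(level, ...) {
  ranks <- c(debug = 1, info = 2, warn = 3, error = 4, quiet = 5)
  if (ranks[[level]] >= ranks[[.logLevel$value]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

.cohortConfigFromList <- function(overrides, seed = NULL) {
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  if (!is.null(seed)) overrides$seed <- as.integer(seed)
  for (nm in c("geneSetSizes", "overlaps", "covariateEffects",
               "outcomeEffects"))
    if (!is.null(overrides[[nm]])) overrides[[nm]] <- unlist(overrides[[nm]])
  do.call(cohortConfig, overrides)
}

#' Run the full pipeline: simulate, normalize, score, associate
#'
#' Drives the package end to end from a run configuration: generates a
#' synthetic cohort, writes its raw artifacts (counts TSV, phenotypes CSV,
#' gene sets GMT, truth JSON), normalizes to log2-CPM, computes the composite
#' scores, runs the association grid, and writes a machine-readable manifest
#' recording the seed and per-model sample sizes.
#'
#' @param config run-configuration list (see [readRunConfig()]) or a path to
#'   a YAML/JSON config file.
#' @param outDir output directory (created if needed); overrides
#'   \code{config$paths$outDir}.
#' @param seed integer seed; overrides \code{config$seed}.
#' @return (invisibly) list with the cohort, score table, grid results and
#'   the manifest.
#' @export
runPipeline <- function(config = list(), outDir = NULL, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(outDir)) outDir <- config$paths$outDir
  if (is.null(outDir)) stop("an output directory is required", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- 1L

  .log("info", "simulate: generating synthetic cohort (seed ", seed, ")")
  ccfg <- .cohortConfigFromList(config$cohort, seed = seed)
  cohort <- generateCohort(ccfg)
  writeCounts(SummarizedExperiment::assay(cohort, "counts"),
              file.path(outDir, "counts.tsv"))
  writePhenotypes(phenotypes(cohort), file.path(outDir, "phenotypes.csv"))
  writeGmt(geneSets(cohort), file.path(outDir, "gene_sets.gmt"))
  truth <- truthRecord(cohort)
  writeTruth(truth[c("covariateEffects", "outcomeEffects", "seed")],
             file.path(outDir, "truth.json"))

  .log("info", "normalize: RLE factors and log2-CPM")
  priorCount <- if (is.null(config$priorCount)) 2 else config$priorCount
  cohort <- normalizeCohort(cohort, priorCount = priorCount)
  nf <- S4Vectors::metadata(cohort)$normFactors
  utils::write.table(
    data.frame(sample_id = colnames(cohort), factor = normFactors(nf)),
    file.path(outDir, "norm_factors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  .log("info", "score: composite senescence scores")
  missingPolicy <- if (is.null(config$missingPolicy)) "error"
                   else config$missingPolicy
  scores <- scoreAll(cohort, missingPolicy = missingPolicy)
  utils::write.csv(scores, file.path(outDir, "scores.csv"), row.names = FALSE)

  .log("info", "associate: model grid")
  grid <- config$grid
  gridArgs <- grid[intersect(names(grid),
                             setdiff(names(formals(runModelGrid)),
                                     c("x", "scoreNames")))]
  tab <- cbind(phenotypes(cohort),
               scores[, setdiff(names(scores), "sample_id"), drop = FALSE])
  results <- do.call(runModelGrid,
                     c(list(x = tab, scoreNames = names(geneSets(cohort))),
                       gridArgs))
  utils::write.csv(results, file.path(outDir, "associations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(results, file.path(outDir, "associations.json"),
                       digits = NA, na = "null")

  manifest <- list(
    seed = as.integer(seed),
    package = "senescore",
    version = as.character(utils::packageVersion("senescore")),
    nSamples = ncol(cohort), nGenes = nrow(cohort),
    priorCount = priorCount,
    models = unique(results[, c("family", "outcome", "score", "n")]),
    failures = attr(results, "failures"),
    files = c("counts.tsv", "phenotypes.csv", "gene_sets.gmt", "truth.json",
              "norm_factors.tsv", "scores.csv", "associations.csv",
              "associations.json"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log("info", "done: outputs in ", outDir)
  invisible(list(cohort = cohort, scores = scores, results = results,
                 manifest = manifest))
}

.parseCliFlags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--"))
      stop(sprintf("flag --%s needs a value", key), call. = FALSE)
    flags[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{normalize}, \code{score},
#' \code{associate}, \code{run-all}.  Flags: \code{--config} (YAML/JSON run
#' config), \code{--seed}, \code{--out} (output directory; required),
#' \code{--counts}, \code{--gmt}, \code{--phenotypes} (per-stage input
#' overrides), \code{--log-level} (debug/info/warn/error/quiet).  Logs go to
#' stderr; result files never mix with logs.  A thin Rscript wrapper is
#' installed at \code{system.file("scripts", "senescore", package =
#' "senescore")}.
#'
#' @param args character vector of command-line arguments
#'   (default \code{commandArgs(trailingOnly = TRUE)}).
#' @return exit status, invisibly: 0 on success, nonzero on error.
#' @export
senescenceCli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: senescore <simulate|normalize|score|associate|run-all>",
    "[--config FILE] [--seed INT] [--out DIR] [--counts FILE] [--gmt FILE]",
    "[--phenotypes FILE] [--log-level LEVEL]")
  fail <- function(msg) {
    message(msg)
    message(usage)
    invisible(1L)
  }
  if (length(args) == 0L) return(fail("no subcommand given"))
  cmd <- args[[1]]
  if (!cmd %in% c("simulate", "normalize", "score", "associate", "run-all"))
    return(fail(sprintf("unknown subcommand '%s'", cmd)))
  flags <- tryCatch(.parseCliFlags(args[-1]),
                    error = function(e) e)
  if (inherits(flags, "error")) return(fail(conditionMessage(flags)))
  if (!is.null(flags[["log-level"]])) .logLevel$value <- flags[["log-level"]]

  status <- tryCatch({
    config <- if (!is.null(flags$config)) readRunConfig(flags$config)
              else list()
    seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else config$seed
    if (is.null(seed)) seed <- 1L
    out <- if (!is.null(flags$out)) flags$out else config$paths$outDir
    if (is.null(out)) stop("--out (or paths.outDir in the config) is required",
                           call. = FALSE)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    pick <- function(flag, key, default)
      if (!is.null(flags[[flag]])) flags[[flag]]
      else if (!is.null(config$paths[[key]])) config$paths[[key]]
      else default

    if (cmd %in% c("simulate", "run-all")) {
      if (cmd == "simulate") {
        ccfg <- .cohortConfigFromList(config$cohort, seed = seed)
        cohort <- generateCohort(ccfg)
        writeCounts(SummarizedExperiment::assay(cohort, "counts"),
                    file.path(out, "counts.tsv"))
        writePhenotypes(phenotypes(cohort), file.path(out, "phenotypes.csv"))
        writeGmt(geneSets(cohort), file.path(out, "gene_sets.gmt"))
        writeTruth(truthRecord(cohort)[c("covariateEffects", "outcomeEffects",
                                         "seed")],
                   file.path(out, "truth.json"))
        .log("info", "simulate: wrote cohort to ", out)
      } else {
        config$seed <- seed
        runPipeline(config, outDir = out, seed = seed)
      }
    } else {
      countsPath <- pick("counts", "counts", file.path(out, "counts.tsv"))
      if (cmd == "normalize") {
        counts <- readCounts(countsPath)
        nf <- rleScaleFactors(counts)
        priorCount <- if (is.null(config$priorCount)) 2 else config$priorCount
        expr <- log2Cpm(counts, nf, priorCount = priorCount)
        utils::write.table(
          data.frame(sample_id = colnames(counts), factor = normFactors(nf)),
          file.path(out, "norm_factors.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
        utils::write.table(df, file.path(out, "log2cpm.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        .log("info", "normalize: wrote factors and log2-CPM to ", out)
      } else if (cmd == "score") {
        counts <- readCounts(countsPath)
        gmt <- readGmt(pick("gmt", "gmt", file.path(out, "gene_sets.gmt")))
        nf <- rleScaleFactors(counts)
        priorCount <- if (is.null(config$priorCount)) 2 else config$priorCount
        expr <- log2Cpm(counts, nf, priorCount = priorCount)
        missingPolicy <- if (is.null(config$missingPolicy)) "error"
                         else config$missingPolicy
        scores <- scoreAll(expr, gmt, missingPolicy = missingPolicy)
        utils::write.csv(scores, file.path(out, "scores.csv"),
                         row.names = FALSE)
        .log("info", "score: wrote ", file.path(out, "scores.csv"))
      } else { # associate
        ph <- readPhenotypes(pick("phenotypes", "phenotypes",
                                  file.path(out, "phenotypes.csv")))
        scores <- utils::read.csv(file.path(out, "scores.csv"),
                                  check.names = FALSE)
        scoreNames <- setdiff(names(scores), "sample_id")
        tab <- merge(ph, scores, by = "sample_id", sort = TRUE)
        grid <- config$grid
        gridArgs <- grid[intersect(names(grid),
                                   setdiff(names(formals(runModelGrid)),
                                           c("x", "scoreNames")))]
        results <- do.call(runModelGrid,
                           c(list(x = tab, scoreNames = scoreNames), gridArgs))
        utils::write.csv(results, file.path(out, "associations.csv"),
                         row.names = FALSE)
        .log("info", "associate: wrote ", file.path(out, "associations.csv"))
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
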