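#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, one or more member genes.
#' Duplicate members within a set and duplicate set names are rejected.
#'
#' @param path GMT file path.
#' @return a [SenGeneSetCollection-class] (roles inferred from set names).
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description and at least one member",
                   i), call. = FALSE)
    nm <- trimws(fields[1])
    members <- trimws(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("malformed GMT line %d: no members", i), call. = FALSE)
    if (anyDuplicated(members))
      stop(sprintf("GMT line %d (set '%s'): duplicate member(s): %s", i, nm,
                   paste(unique(members[duplicated(members)]), collapse = ", ")),
           call. = FALSE)
    if (nm %in% names(sets))
      stop(sprintf("GMT line %d: duplicate set name '%s'", i, nm),
           call. = FALSE)
    sets[[nm]] <- members
  }
  SenGeneSetCollection(sets)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [SenGeneSetCollection-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "SenGeneSetCollection"))
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, geneSetRoles(collection)[[nm]], collection[[nm]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count matrix (TSV or MatrixMarket)
#'
#' TSV: first column gene id, header row of sample ids.  MTX: MatrixMarket
#' coordinate file with gene and sample identifiers in sidecar files
#' (\code{<stem>_genes.txt}, \code{<stem>_samples.txt}).  Entries must be
#' nonnegative integers; violations are reported with their coordinates.
#'
#' @param path counts file path.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param genesPath,samplesPath sidecar paths for MTX (defaults derived from
#'   \code{path}).
#' @return integer matrix, genes x samples.
#' @export
readCounts <- function(path, format = c("tsv", "mtx"),
                       genesPath = NULL, samplesPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("counts file not found: %s", path),
                               call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- genes
  } else {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(genesPath)) genesPath <- paste0(stem, "_genes.txt")
    if (is.null(samplesPath)) samplesPath <- paste0(stem, "_samples.txt")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genesPath)
    colnames(m) <- readLines(samplesPath)
  }
  if (!is.numeric(m))
    stop("count matrix contains non-numeric entries", call. = FALSE)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at gene '%s', sample '%s': %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 format(m[bad[1, 1], bad[1, 2]])), call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers in counts file", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix (TSV or MatrixMarket with sidecars)
#'
#' @param counts integer genes x samples matrix.
#' @param path output path (for MTX, sidecar gene/sample files are written
#'   next to it).
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @return the path, invisibly.
#' @export
writeCounts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  counts <- asCountMatrix(counts, minSamples = 1L, minGenes = 1L)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(stem, "_genes.txt"))
    writeLines(colnames(counts), paste0(stem, "_samples.txt"))
  }
  invisible(path)
}

.validatePhenotypes <- function(ph) {
  if ("weight" %in% names(ph)) {
    bad <- !is.na(ph$weight) & ph$weight <= 0
    if (any(bad))
      stop(sprintf("nonpositive survey weight in row(s): %s",
                   paste(utils::head(which(bad), 5), collapse = ", ")),
           call. = FALSE)
  }
  if ("vital_status" %in% names(ph)) {
    bad <- !is.na(ph$vital_status) & !ph$vital_status %in% 1:4
    if (any(bad))
      stop(sprintf("unknown vital-status code(s): %s",
                   paste(unique(ph$vital_status[bad]), collapse = ", ")),
           call. = FALSE)
  }
  if ("multimorbidity" %in% names(ph)) {
    mm <- ph$multimorbidity
    bad <- !is.na(mm) & (mm < 0 | mm > 5 | mm != round(mm))
    if (any(bad))
      stop("multimorbidity must be an integer in [0, 5]", call. = FALSE)
  }
  if ("cognition" %in% names(ph)) {
    bad <- !is.na(ph$cognition) & (ph$cognition < 0 | ph$cognition > 27)
    if (any(bad))
      stop("cognition must lie in [0, 27]", call. = FALSE)
  }
  invisible(ph)
}

#' Read a phenotype table from CSV
#'
#' Validates per-sample invariants (positive weights, vital status in 1-4,
#' multimorbidity 0-5, cognition 0-27); missing cells are preserved as
#' missing (complete-case handling belongs to the model stage).  Known
#' categorical columns are restored as factors with the declared reference
#' level first.
#'
#' @param path CSV path with a header row.
#' @return data.frame keyed by \code{sample_id}.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop(sprintf("phenotype file not found: %s", path),
                               call. = FALSE)
  ph <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lvls <- list(age_group = .AGE_LEVELS, race = .RACE_LEVELS,
               education = .EDU_LEVELS, bmi_class = .BMI_LEVELS)
  for (nm in names(lvls))
    if (nm %in% names(ph)) {
      extra <- setdiff(stats::na.omit(unique(ph[[nm]])), lvls[[nm]])
      ph[[nm]] <- factor(ph[[nm]], levels = c(lvls[[nm]], extra))
    }
  if ("batch" %in% names(ph)) ph$batch <- factor(ph$batch)
  .validatePhenotypes(ph)
  if ("sample_id" %in% names(ph)) rownames(ph) <- ph$sample_id
  ph
}

#' Write a phenotype table as CSV
#' @param ph phenotype data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePhenotypes <- function(ph, path) {
  utils::write.csv(ph, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write a truth record as JSON
#' @param truth truth list from the generator.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognised keys: \code{paths} (counts, gmt, phenotypes, outDir),
#' \code{priorCount}, \code{missingPolicy}, \code{grid} (families, cv, cvK,
#' covariates, ...), \code{seed}, \code{cohort} (overrides for
#' [cohortConfig()]).  Missing keys fall back to defaults; \code{k >= 2} and
#' \code{priorCount > 0} are enforced.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return named list of run options.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(priorCount = 2, missingPolicy = "error", seed = 1L,
                   grid = list(), cohort = list(), paths = list())
  cfg <- utils::modifyList(defaults, cfg)
  if (cfg$priorCount <= 0) stop("priorCount must be > 0", call. = FALSE)
  if (!is.null(cfg$grid$cvK) && cfg$grid$cvK < 2)
    stop("cv folds k must be >= 2", call. = FALSE)
  cfg
}
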