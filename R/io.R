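## CSV input/output. Column vocabulary follows the field's convention for
## Delta-Delta-Cq tables: housek0/target0 are the control (undigested)
## channels, housek1/target1 the test (digested) channels.

#' Read a Cq table from CSV
#'
#' Two schemas are supported. \code{schema = "estimate"}: one row per bulk
#' sample with columns \code{n}, \code{housek0}, \code{target0},
#' \code{housek1}, \code{target1} and optionally \code{sampleId}; returns a
#' \linkS4class{BulkCqData}. \code{schema = "calibrate"}: long format with
#' columns \code{ratio}, \code{gene} (\code{housek}/\code{target}),
#' \code{condition} (0/1), \code{replicate}, \code{cq}; missing cells are
#' simply absent rows (the unpaired design); returns a
#' \linkS4class{KnownRatioData}. Validation failures are reported with row
#' numbers.
#'
#' @param path CSV file path (header required, '.' decimal separator).
#' @param schema \code{"estimate"} or \code{"calibrate"}.
#' @return A \linkS4class{BulkCqData} or \linkS4class{KnownRatioData}.
#' @export
readCqTable <- function(path, schema = c("estimate", "calibrate")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .badRows <- function(bad, what) {
    if (any(bad))
      stop(sprintf("%s in row(s) %s of %s", what,
                   paste(which(bad), collapse = ", "), path), call. = FALSE)
  }
  if (schema == "estimate") {
    need <- c("n", .cqCols)
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    for (cc in .cqCols) {
      v <- suppressWarnings(as.numeric(df[[cc]]))
      .badRows(!is.finite(v), sprintf("non-numeric or missing '%s'", cc))
      df[[cc]] <- v
    }
    nv <- suppressWarnings(as.numeric(df$n))
    .badRows(!is.finite(nv) | nv < 1 | nv != round(nv),
             "pool size 'n' must be a positive integer")
    BulkCqData(housek0 = df$housek0, target0 = df$target0,
               housek1 = df$housek1, target1 = df$target1,
               n = as.integer(nv),
               sampleId = if ("sampleId" %in% names(df))
                 as.character(df$sampleId) else NULL)
  } else {
    need <- c("ratio", "gene", "condition", "replicate", "cq")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    rv <- suppressWarnings(as.numeric(df$ratio))
    .badRows(!is.finite(rv) | rv < 0 | rv > 1, "ratio outside [0, 1]")
    .badRows(!df$gene %in% c("housek", "target"),
             "gene must be 'housek' or 'target'")
    .badRows(!df$condition %in% c(0, 1), "condition must be 0 or 1")
    cv <- suppressWarnings(as.numeric(df$cq))
    .badRows(!is.finite(cv), "non-numeric or missing 'cq'")
    KnownRatioData(ratio = rv, gene = df$gene,
                   condition = as.integer(df$condition),
                   replicate = df$replicate, cq = cv)
  }
}

#' Write a Cq table or fit result to CSV
#'
#' @param x a \linkS4class{BulkCqData}, \linkS4class{KnownRatioData} or fit
#'   object (\linkS4class{FreqFit} / \linkS4class{CalibFit}; written as one
#'   row per parameter).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCqTable <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit result to JSON with provenance
#'
#' Serializes the parameter table together with the package version and the
#' fit metadata (kernel, fixed parameters, convergence), so a result file is
#' self-describing.
#'
#' @param fit a \linkS4class{FreqFit} or \linkS4class{CalibFit}.
#' @param path output JSON path.
#' @param seed optional seed to record.
#' @return \code{path}, invisibly.
#' @export
writeFitJson <- function(fit, path, seed = NULL) {
  stopifnot(is(fit, "CqFit"))
  out <- list(
    tool = "bulkCq",
    version = as.character(packageVersion("bulkCq")),
    seed = seed,
    converged = fit@converged,
    intervalSuccess = fit@success,
    loglik = fit@loglik,
    level = fit@level,
    parameters = as.data.frame(fit))
  if (is(fit, "FreqFit")) {
    out$kernel <- fit@kernel
    out$fixed <- as.list(fit@fixed)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Average technical replicates of bulk-sample Cq measurements
#'
#' Computes the arithmetic mean of each Cq channel per sample before
#' estimation. Note the measurement-error parameter then refers to the SD of
#' an averaged Cq, which is smaller than the per-well SD; this is immaterial
#' as long as the number of technical replicates is the same for every bulk
#' sample, and a warning is raised when it is not.
#'
#' @param df data.frame with columns \code{sampleId}, \code{n},
#'   \code{housek0}, \code{target0}, \code{housek1}, \code{target1}; one row
#'   per technical replicate.
#' @return A \linkS4class{BulkCqData} with one row per sample.
#' @examples
#' df <- data.frame(sampleId = c("a", "a", "b"), n = 4,
#'                  housek0 = c(20, 20.2, 21), target0 = c(20.5, 20.7, 21.5),
#'                  housek1 = c(22, 22.2, 23), target1 = c(24, 24.4, 25))
#' averageTechReps(df)
#' @export
averageTechReps <- function(df) {
  need <- c("sampleId", "n", .cqCols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  counts <- table(df$sampleId)
  if (length(unique(counts)) > 1L)
    warning("unbalanced technical replicate counts across samples (",
            paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
            "); the effective Cq error SD then differs between samples",
            call. = FALSE)
  ids <- unique(df$sampleId)
  agg <- lapply(ids, function(id) {
    s <- df[df$sampleId == id, ]
    if (length(unique(s$n)) > 1L)
      stop("pool size 'n' differs between replicates of sample ", id,
           call. = FALSE)
    c(n = s$n[1L], colMeans(s[, .cqCols]))
  })
  m <- do.call(rbind, agg)
  BulkCqData(housek0 = m[, "housek0"], target0 = m[, "target0"],
             housek1 = m[, "housek1"], target1 = m[, "target1"],
             n = as.integer(m[, "n"]), sampleId = ids)
}
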