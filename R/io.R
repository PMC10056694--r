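# Readers/writers for the tabular artifacts: count matrices (TSV/CSV,
# '#'-comment provenance headers), correlation matrices with sidecar
# metadata, and count pairs.

#' Read a count matrix from TSV/CSV
#'
#' Expects a header row and feature identifiers in the first column. Entries
#' must be non-negative integers; a non-integer or negative entry is
#' rejected with its row/column context, as are duplicate identifiers.
#' Lines starting with '#' are comments.
#'
#' @param path file path; `.csv` is parsed comma-separated, anything else
#'   tab-separated.
#' @param orientation "features_by_samples" (default) or
#'   "samples_by_features" (transposed on read, so the returned object is
#'   always features x samples).
#' @return a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay.
#' @export
readCountMatrix <- function(path,
                            orientation = c(
                              "features_by_samples",
                              "samples_by_features"
                            )) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    read.delim(path,
      sep = sep, header = TRUE, comment.char = "#",
      check.names = FALSE, stringsAsFactors = FALSE
    ),
    error = function(e) {
      stop("failed to parse ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (ncol(df) < 2) stop("no data columns in ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(
      as.numeric(m), nrow(m)
    ))) & !is.na(m), arr.ind = TRUE)[1, , drop = TRUE]
    stop("non-numeric entry at row '", ids[bad[1]], "', column '",
      colnames(m)[bad[2]], "' in ", path,
      call. = FALSE
    )
  }
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("entry '", m[bad[1, 1], bad[1, 2]], "' at row '", ids[bad[1, 1]],
      "', column '", colnames(m)[bad[1, 2]], "' in ", path,
      " is not a non-negative integer",
      call. = FALSE
    )
  }
  rownames(m) <- ids
  if (orientation == "samples_by_features") m <- t(m)
  SummarizedExperiment::SummarizedExperiment(assays = list(counts = m))
}

#' Write a count matrix as TSV with a provenance header
#'
#' @param x count matrix or SummarizedExperiment (features x samples).
#' @param path output path.
#' @param seed seed recorded in the provenance header.
#' @param cfg free-form configuration string fingerprinted in the header.
#' @export
writeCountMatrix <- function(x, path, seed = NA, cfg = "") {
  m <- .countMatrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(seed, cfg), con)
  writeLines(paste(c("feature", colnames(m)), collapse = "\t"), con)
  write.table(m, con,
    sep = "\t", quote = FALSE, col.names = FALSE,
    row.names = TRUE
  )
  invisible(path)
}

#' Write a correlation matrix as TSV plus sidecar metadata
#'
#' Values go to `path` (row/column feature identifiers preserved); the
#' method tag and the per-entry failure mask go to `<path>.meta.json`.
#'
#' @param corr a [CorrMatrix-class].
#' @param path output path.
#' @param seed,cfg provenance header fields.
#' @export
writeCorrMatrix <- function(corr, path, seed = NA, cfg = "") {
  stopifnot(methods::is(corr, "CorrMatrix"))
  m <- corr@values
  con <- file(path, "w")
  writeLines(.provenanceHeader(seed, cfg), con)
  writeLines(paste(c("feature", colnames(m)), collapse = "\t"), con)
  write.table(m, con,
    sep = "\t", quote = FALSE, col.names = FALSE,
    row.names = TRUE
  )
  close(con)
  failedMask <- startsWith(corr@status, "failed")
  dim(failedMask) <- dim(corr@status) # startsWith drops matrix dims
  failed <- which(failedMask, arr.ind = TRUE)
  meta <- list(
    method = corr@method,
    rows = rownames(m), cols = colnames(m),
    failedRow = as.integer(failed[, 1]), failedCol = as.integer(failed[, 2])
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a correlation matrix written by [writeCorrMatrix()]
#'
#' @param path path given to the writer.
#' @return a [CorrMatrix-class] (failure flags restored from the sidecar).
#' @export
readCorrMatrix <- function(path) {
  df <- read.delim(path,
    sep = "\t", comment.char = "#", check.names = FALSE,
    stringsAsFactors = FALSE
  )
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  metaPath <- paste0(path, ".meta.json")
  method <- "matrix"
  status <- matrix("ok", nrow(m), ncol(m), dimnames = dimnames(m))
  if (file.exists(metaPath)) {
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    method <- meta$method
    if (length(meta$failedRow)) {
      status[cbind(meta$failedRow, meta$failedCol)] <- "failed: (from file)"
    }
  }
  methods::new("CorrMatrix", values = m, method = method, status = status)
}

#' Write a simulated count pair as TSV
#'
#' @param pair two-column matrix from [rbzinb()] or
#'   [simulateLognormalPair()].
#' @param path output path.
#' @param seed,cfg provenance header fields.
#' @export
writeCountPair <- function(pair, path, seed = NA, cfg = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(seed, cfg), con)
  writeLines("x1\tx2", con)
  write.table(pair, con,
    sep = "\t", quote = FALSE, col.names = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a count pair written by [writeCountPair()]
#'
#' @param path file path.
#' @return two-column integer matrix.
#' @export
readCountPair <- function(path) {
  df <- read.delim(path,
    sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE
  )
  as.matrix(df[, c("x1", "x2")])
}
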