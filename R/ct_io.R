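## Reading and writing the tabular shapes the pipeline touches: long qPCR
## exports (one row per reaction), wide Ct matrices, sample covariates, and
## key/value run reports. Only text exports are supported; instrument binary
## formats are out of scope.

#' Column dialect for long qPCR exports
#'
#' Instrument export schemas vary; the dialect maps the column names found in
#' a file onto the canonical fields. `nondetect` lists the Ct tokens treated
#' as a non-detect (a reaction that never crossed threshold).
#'
#' @param sample_id,mirna_id,replicate,ct,amp_score,cq_conf column names in
#'   the file. `amp_score` and `cq_conf` may be absent from the file.
#' @param nondetect character tokens read as non-detect.
#' @return a named list usable as the `dialect` of [readCtLong()].
#' @export
ctDialect <- function(sample_id = "sample_id", mirna_id = "mirna_id",
                      replicate = "replicate", ct = "ct",
                      amp_score = "amp_score", cq_conf = "cq_conf",
                      nondetect = c("Undetermined", "", "NA")) {
  list(sample_id = sample_id, mirna_id = mirna_id, replicate = replicate,
       ct = ct, amp_score = amp_score, cq_conf = cq_conf,
       nondetect = nondetect)
}

.detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.numOrNA <- function(x, col) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "")
  if (length(bad))
    stop("unparsable ", col, " value '", x[bad[1]], "' at data row ", bad[1],
         call. = FALSE)
  v
}

#' Read a long-format qPCR export
#'
#' One row per reaction: sample, miRNA, replicate, Ct, and optional
#' amplification-score / Cq-confidence quality metrics. Empty or
#' `"Undetermined"` Ct fields become non-detects (`NA` Ct). The field
#' separator (comma or tab) is auto-detected from the header.
#'
#' @param path file path.
#' @param dialect column mapping from [ctDialect()].
#' @return a `data.frame` of reading records with columns `sample_id`,
#'   `mirna_id`, `replicate`, `ct`, `amp_score`, `cq_conf`.
#' @export
readCtLong <- function(path, dialect = ctDialect()) {
  stopifnot(file.exists(path))
  sep <- .detectSep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  required <- c("sample_id", "mirna_id", "replicate", "ct")
  for (field in required) {
    if (!dialect[[field]] %in% names(raw))
      stop("required column '", dialect[[field]], "' (", field,
           ") not found in ", path, call. = FALSE)
  }
  ct_raw <- raw[[dialect$ct]]
  is_nd <- is.na(ct_raw) | ct_raw %in% dialect$nondetect
  ct <- rep(NA_real_, nrow(raw))
  ct[!is_nd] <- .numOrNA(ct_raw[!is_nd], "Ct")
  if (any(ct[!is_nd] <= 0, na.rm = TRUE))
    stop("Ct values must be positive", call. = FALSE)
  getOpt <- function(field) {
    if (dialect[[field]] %in% names(raw))
      .numOrNA(raw[[dialect[[field]]]], field)
    else rep(NA_real_, nrow(raw))
  }
  rec <- data.frame(
    sample_id = raw[[dialect$sample_id]],
    mirna_id = raw[[dialect$mirna_id]],
    replicate = as.integer(.numOrNA(raw[[dialect$replicate]], "replicate")),
    ct = ct,
    amp_score = getOpt("amp_score"),
    cq_conf = getOpt("cq_conf"),
    stringsAsFactors = FALSE)
  if (any(rec$replicate < 1L))
    stop("replicate indices must be >= 1", call. = FALSE)
  key <- paste(rec$sample_id, rec$mirna_id, rec$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (sample_id, mirna_id, replicate) at data row ",
         which(duplicated(key))[1], call. = FALSE)
  rec[order(rec$sample_id, rec$mirna_id, rec$replicate, method = "radix"), ,
      drop = FALSE]
}

#' Write reading records as a long-format table
#'
#' Inverse of [readCtLong()]: non-detect Cts are written as `"Undetermined"`,
#' numeric fields at full precision so that write-then-read round-trips.
#'
#' @param records reading records (`data.frame`).
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeCtLong <- function(records, path, sep = ",") {
  out <- records
  ctc <- .fmtNum(out$ct)
  ctc[is.na(out$ct)] <- "Undetermined"
  out$ct <- ctc
  out$amp_score <- .fmtNum(out$amp_score)
  out$cq_conf <- .fmtNum(out$cq_conf)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pivot replicate-aggregated reading records to a CtExperiment
#'
#' Records must already hold one row per sample x miRNA (run
#' [aggregateReplicates()] first). Pairs absent from the records, like
#' non-detect records, yield non-detect cells. Samples and miRNAs are put in
#' canonical (lexicographic) order, so reading order never affects the
#' matrix.
#'
#' @param records replicate-aggregated reading records.
#' @param sampleData optional per-sample covariates (see [CtExperiment()]).
#' @return a [CtExperiment-class].
#' @export
ctFromRecords <- function(records, sampleData = NULL) {
  key <- paste(records$sample_id, records$mirna_id, sep = "\r")
  if (anyDuplicated(key))
    stop("records contain replicate rows for the same sample x miRNA; ",
         "aggregate replicates first (aggregateReplicates())", call. = FALSE)
  samples <- .canonicalSort(unique(records$sample_id))
  mirnas <- .canonicalSort(unique(records$mirna_id))
  m <- matrix(NA_real_, length(mirnas), length(samples),
              dimnames = list(mirnas, samples))
  m[cbind(match(records$mirna_id, mirnas),
          match(records$sample_id, samples))] <- records$ct
  CtExperiment(m, sampleData = sampleData)
}

#' Flatten a CtExperiment back to reading records
#'
#' @param x a [CtExperiment-class].
#' @return a `data.frame` of one record per sample x miRNA (replicate 1),
#'   non-detect cells carrying `NA` Ct.
#' @export
ctToRecords <- function(x) {
  m <- ctMatrix(x)
  m[!detected(x)] <- NA  # imputed values revert to non-detect records
  data.frame(sample_id = rep(colnames(m), each = nrow(m)),
             mirna_id = rep(rownames(m), times = ncol(m)),
             replicate = 1L,
             ct = as.vector(m),
             amp_score = NA_real_, cq_conf = NA_real_,
             stringsAsFactors = FALSE)
}

#' Read / write a wide Ct matrix
#'
#' Wide format: first column `sample_id`, remaining columns one per miRNA,
#' `"NA"` marking non-detects. Values are written at full precision so that
#' write-then-read reproduces the matrix exactly.
#'
#' @param path file path.
#' @param sampleData optional covariates passed to [CtExperiment()].
#' @return `readCtWide()`: a [CtExperiment-class]; writers return the path
#'   invisibly.
#' @export
readCtWide <- function(path, sampleData = NULL) {
  stopifnot(file.exists(path))
  sep <- .detectSep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (names(raw)[1] != "sample_id")
    stop("wide format requires 'sample_id' as the first column", call. = FALSE)
  m <- t(as.matrix(raw[, -1, drop = FALSE]))
  storage.mode(m) <- "double"
  colnames(m) <- raw$sample_id
  CtExperiment(m, sampleData = sampleData)
}

#' @rdname readCtWide
#' @param x a [CtExperiment-class] or [NormalizedCt-class] to write.
#' @param sep field separator.
#' @export
writeCtMatrix <- function(x, path, sep = ",") {
  m <- if (is(x, "NormalizedCt")) deltaCt(x) else ctMatrix(x)
  wide <- cbind(sample_id = colnames(m),
                as.data.frame(t(matrix(.fmtNum(m), nrow(m), ncol(m),
                                       dimnames = dimnames(m)))))
  utils::write.table(wide, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample covariate table
#'
#' Delimited file with columns `sample_id`, `age` (years), `sex`.
#'
#' @param path file path.
#' @return a `data.frame` keyed by `sample_id`.
#' @export
readSampleInfo <- function(path) {
  stopifnot(file.exists(path))
  sep <- .detectSep(path)
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"")
  if (!"sample_id" %in% names(out))
    stop("covariate file requires a 'sample_id' column", call. = FALSE)
  out
}

#' Write a QC report as structured key/value text
#'
#' @param report a [QCReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQCReport <- function(report, path) {
  lines <- c("# EndoCt QC report",
             vapply(names(report@thresholds), function(nm)
               paste0("threshold.", nm, "\t", report@thresholds[[nm]]),
               character(1)),
             vapply(names(report@readingsRemoved), function(nm)
               paste0("readings_removed.", nm, "\t",
                      report@readingsRemoved[[nm]]), character(1)),
             paste0("samples_removed\t", nrow(report@samplesRemoved)),
             vapply(seq_len(nrow(report@samplesRemoved)), function(i)
               paste0("sample_removed\t", report@samplesRemoved$sample_id[i],
                      "\t", report@samplesRemoved$n_detected[i]), character(1)),
             paste0("mirnas_removed\t", nrow(report@mirnasRemoved)),
             vapply(seq_len(nrow(report@mirnasRemoved)), function(i)
               paste0("mirna_removed\t", report@mirnasRemoved$mirna_id[i],
                      "\t", report@mirnasRemoved$missing_frac[i]),
               character(1)),
             paste0("cells_imputed\t", report@cellsImputed))
  writeLines(lines, path)
  invisible(path)
}
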