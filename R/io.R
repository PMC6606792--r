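## File-format adapters: RFC-4180 CSV for signals and feature tables, and a
## minimal WFDB reader/writer (header + 16-bit little-endian signal files).
## No installed R package reads WFDB, so the format-16 subset used here is
## implemented directly.

csvHeaderComment <- function(seed = NULL, config = NULL) {
  h <- sprintf("# rdisen %s", as.character(utils::packageVersion("rdisen")))
  if (!is.null(seed)) h <- paste0(h, " seed=", seed)
  if (!is.null(config))
    h <- paste0(h, " config-hash=",
                sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9)
  h
}

#' Read signals from a CSV file
#'
#' Accepts a single-column file (one signal) or a multi-column file (one
#' signal per column, header row optional). Comment lines starting with `#`
#' are ignored. Non-numeric cells raise a parse error naming the position.
#'
#' @param path CSV file path.
#' @return list of numeric signals.
#' @export
readSignalCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty CSV: ", path, call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  hasHeader <- suppressWarnings(any(is.na(as.numeric(cells[[1]]))))
  if (hasHeader) { lines <- lines[-1]; cells <- cells[-1] }
  ncol <- length(cells[[1]])
  mat <- matrix(NA_real_, nrow = length(cells), ncol = ncol)
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (length(v) != ncol || anyNA(v))
      stop(sprintf("parse error in %s at data line %d", path, i), call. = FALSE)
    mat[i, ] <- v
  }
  lapply(seq_len(ncol), function(j) mat[, j])
}

#' Write signals to a CSV file
#'
#' One signal per column; a `#` comment line records the package version and
#' seed/config hash for provenance.
#'
#' @param signals list of numeric vectors (equal lengths) or one vector.
#' @param path output path.
#' @param seed,config optional provenance recorded in the header comment.
#' @export
writeSignalCsv <- function(signals, path, seed = NULL, config = NULL) {
  if (is.numeric(signals)) signals <- list(signals)
  mat <- do.call(cbind, signals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csvHeaderComment(seed, config), con)
  utils::write.table(mat, con, sep = ",", row.names = FALSE,
                     col.names = paste0("signal", seq_len(ncol(mat))))
}

#' Write a feature table to CSV
#'
#' Columns are the 25 canonical feature names
#' (`RdisEn, M1..M8, Mi1..Mi8, Ma1..Ma8`) plus a final `label` column.
#'
#' @param table feature data.frame from [extractFeatureTable()].
#' @param path output path.
#' @param seed,config optional provenance for the header comment.
#' @export
writeFeatureCsv <- function(table, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csvHeaderComment(seed, config), con)
  utils::write.csv(table, con, row.names = FALSE)
}

#' Read a feature table written by [writeFeatureCsv()]
#'
#' @param path CSV path.
#' @return data.frame with feature columns and a factor `label`.
#' @export
readFeatureCsv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if ("label" %in% names(df)) df$label <- factor(df$label)
  df
}

#' Write an ECG record as a minimal WFDB record
#'
#' Writes `<id>.hea` and `<id>.dat` (format 16: 16-bit two's-complement
#' little-endian integers) with the given gain in ADC units per mV.
#'
#' @param rec an [ecgRecord()].
#' @param dir output directory.
#' @param gain ADC units per mV (default 200).
#' @return the record name (invisibly).
#' @export
writeWfdb <- function(rec, dir, gain = 200) {
  stopifnot(inherits(rec, "ecgRecord"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adc <- as.integer(round(rec$samples * gain))
  if (any(abs(adc) > 32767)) stop("samples overflow 16-bit range at this gain", call. = FALSE)
  name <- rec$id
  hea <- c(sprintf("%s 1 %g %d", name, rec$fs, length(adc)),
           sprintf("%s.dat 16 %g 16 0 %d 0 0 ECG", name, gain, adc[1]))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  writeBin(adc, file.path(dir, paste0(name, ".dat")), size = 2, endian = "little")
  invisible(name)
}

#' Read a minimal WFDB record (format 16)
#'
#' Parses the header for the sampling rate, gain and sample count and decodes
#' the 16-bit little-endian signal file. Multi-signal records are read
#' interleaved and the requested channel returned.
#'
#' @param path path to the `.hea` file (or record name without extension).
#' @param channel signal channel to return (default 1).
#' @return an [ecgRecord()] with samples in mV.
#' @export
readWfdb <- function(path, channel = 1) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea, call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("malformed WFDB header line: ", lines[1], call. = FALSE)
  name <- top[1]; nsig <- as.integer(top[2])
  fs <- as.numeric(top[3]); nSamp <- as.integer(top[4])
  if (channel > nsig) stop("channel out of range", call. = FALSE)
  sigLine <- strsplit(trimws(lines[1 + channel]), "\\s+")[[1]]
  if (sigLine[2] != "16")
    stop("only WFDB format 16 is supported (got ", sigLine[2], ")", call. = FALSE)
  gain <- as.numeric(sub("\\(.*", "", sigLine[3]))
  if (!is.finite(gain) || gain == 0) gain <- 200
  datPath <- file.path(dirname(hea), strsplit(trimws(lines[2]), "\\s+")[[1]][1])
  raw <- readBin(datPath, integer(), n = nSamp * nsig, size = 2,
                 endian = "little", signed = TRUE)
  samples <- raw[seq(channel, length(raw), by = nsig)] / gain
  ecgRecord(samples, fs, id = name)
}
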