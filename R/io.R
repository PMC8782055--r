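#' Read a two-column spectrum file
#'
#' Parses wavenumber/intensity text: comma- or whitespace-separated, `#`
#' comment lines allowed anywhere. Descending-wavenumber files are reversed
#' to the ascending canonical order; duplicate wavenumbers are an error, and
#' non-numeric rows are reported with their line number.
#'
#' @param path File path.
#' @param min_points Minimum accepted grid length (the spectral analyses
#'   themselves require at least 16 points; toy files may be shorter).
#' @param meta Metadata list attached to the spectrum.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, min_points = 2, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  # a single leading non-numeric row is a column header
  if (length(fields) > 1 &&
      anyNA(suppressWarnings(as.numeric(fields[[1]])))) {
    fields <- fields[-1]; lines <- lines[-1]; lineno <- lineno[-1]
  }
  bad <- which(vapply(fields, length, integer(1)) < 2)
  parse_fail <- function(i)
    stop("parse error at line ", lineno[i], " of ", path, ": ",
         sQuote(raw[lineno[i]]), call. = FALSE)
  if (length(bad)) parse_fail(bad[1])
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 1)))
  y <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  if (anyNA(w) || anyNA(y)) parse_fail(which(is.na(w) | is.na(y))[1])
  if (length(w) < min_points)
    stop("too short: ", path, " has ", length(w), " points (need >= ",
         min_points, ")", call. = FALSE)
  if (anyDuplicated(w))
    stop("duplicate wavenumber in ", path, ": ", w[anyDuplicated(w)],
         call. = FALSE)
  spectrum(w, y, meta = c(meta, list(source = path)))
}

#' Write a spectrum as CSV
#'
#' Two columns, `wavenumber_cm1` and `intensity`, full double precision.
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  df <- data.frame(wavenumber_cm1 = spec$wavenumbers,
                   intensity = spec$intensities)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dose-response CSV
#'
#' Expected columns: `ion`, `dose_gy`, `response_kind` and either `response`
#' or the count pair `n`, `n0` (survival responses are then derived as
#' N/N0). Extra columns are ignored. A missing required column or an invalid
#' `response_kind` is a schema error naming the offender.
#'
#' @param path CSV path (UTF-8, header required).
#' @return A [dose_response()].
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("ion", "dose_gy", "response_kind"))
    if (!col %in% names(df))
      stop("schema error: missing required column ", sQuote(col),
           call. = FALSE)
  kind <- unique(df$response_kind)
  if (length(kind) != 1L || !kind %in% c("survival", "release_ratio"))
    stop("schema error: response_kind must be uniformly 'survival' or ",
         "'release_ratio', got ", paste(sQuote(kind), collapse = ", "),
         call. = FALSE)
  if (any(df$dose_gy < 0))
    stop("validation error: negative dose", call. = FALSE)
  has_counts <- all(c("n", "n0") %in% names(df))
  if (!"response" %in% names(df)) {
    if (!has_counts)
      stop("schema error: need a 'response' column or both 'n' and 'n0'",
           call. = FALSE)
    df$response <- df$n / df$n0
  }
  dose_response(df$ion[1], df$dose_gy, df$response, kind,
                n = if (has_counts) df$n else NULL,
                n0 = if (has_counts) df$n0 else NULL,
                meta = list(source = path))
}

#' Write a dose-response dataset as CSV
#'
#' @param data A [dose_response()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(data, path) {
  stopifnot(inherits(data, "dose_response"))
  df <- data.frame(ion = data$ion, dose_gy = data$doses,
                   response = data$responses,
                   response_kind = data$response_kind)
  if (!is.null(data$n)) { df$n <- data$n; df$n0 <- data$n0 }
  utils::write.csv(format(df, digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record serialized next to every output batch: package
#' version, a configuration snapshot, MD5 digests of the input files, seeds
#' and a timestamp. Re-running with an identical manifest (same inputs,
#' config and seeds) reproduces deterministic outputs bit-identically; the
#' digests change whenever an input file changes.
#'
#' @param inputs Character vector of input file paths (digested).
#' @param config Named list snapshot of parameters.
#' @param seeds Named or plain integer vector of seeds in play.
#' @return List of class `"run_manifest"`.
#' @export
run_manifest <- function(inputs = character(), config = list(),
                         seeds = integer()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(tool = "sporehit",
                 version = as.character(utils::packageVersion("sporehit")),
                 config = config,
                 input_digests = digests,
                 seeds = seeds,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' Write analysis records as JSON/CSV twins
#'
#' Serializes a list of records (e.g. fit summaries) as a JSON file and,
#' when the records are flat, a CSV twin with the same stem; a run manifest
#' is written alongside as `<stem>_manifest.json`.
#'
#' @param records List of named lists (one per record), or a data frame.
#' @param path Output JSON path (`.json`); the CSV twin replaces the
#'   extension.
#' @param manifest Optional [run_manifest()].
#' @return Named list of the files written, invisibly.
#' @export
write_results <- function(records, path, manifest = NULL) {
  if (is.data.frame(records)) records <- split_rows(records)
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- list(json = path)
  flat <- length(records) == 0L ||
    all(vapply(records, function(r)
      all(lengths(r) == 1L) && !any(vapply(r, is.list, logical(1))),
      logical(1)))
  if (flat) {
    csv <- sub("\\.json$", ".csv", path)
    if (identical(csv, path)) csv <- paste0(path, ".csv")
    df <- if (length(records))
      do.call(rbind, lapply(records, function(r) as.data.frame(r))) else
        data.frame()
    utils::write.csv(df, csv, row.names = FALSE)
    files$csv <- csv
  }
  if (!is.null(manifest)) {
    mpath <- sub("\\.json$", "_manifest.json", path)
    jsonlite::write_json(unclass(manifest), mpath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files$manifest <- mpath
  }
  invisible(files)
}

split_rows <- function(df) lapply(seq_len(nrow(df)), function(i)
  as.list(df[i, , drop = FALSE]))

#' Read back analysis records written by [write_results()]
#'
#' @param path JSON path.
#' @return List of records.
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Summarize a hit-model fit as a flat record
#'
#' @param fit A `"hit_fit"`.
#' @param ci Optional [bootstrap_ci()] result.
#' @param extra Extra scalar fields to append.
#' @return Named list suitable for [write_results()].
#' @export
fit_record <- function(fit, ci = NULL, extra = list()) {
  rec <- list(k = fit$k, lambda_gy = fit$lambda_gy,
              lambda_se = fit$lambda_se, amplitude = fit$amplitude,
              baseline = fit$baseline, residual_ss = fit$residual_ss)
  if (!is.null(ci)) {
    rec$ci_lower <- ci$lower
    rec$ci_upper <- ci$upper
    rec$n_boot <- length(ci$lambda_boot) + ci$n_failed
  }
  c(rec, extra)
}
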