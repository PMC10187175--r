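# Delimited-text schemas shared by all pipeline stages. Tables are CSV with
# a header row; metadata (seed, config hash, package version) is embedded as
# leading `#`-comment lines so reruns with identical config are
# byte-identical and self-describing.

event_required_cols <- c("n_ch1_only", "n_ch2_only", "n_double", "total_events")

#' Validate a gated event-count table
#'
#' Enforces the event-table schema invariants: required count columns
#' present, all counts non-negative, class counts (including noise and the
#' optional dye-only class) summing to `total_events`, and dilution factors
#' >= 1. Violations raise an error naming the offending rows.
#'
#' @param data Data frame to validate.
#' @return `data`, invisibly, if valid.
#' @export
validate_event_table <- function(data) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(event_required_cols, names(data))
  if (length(missing)) {
    abort(paste0("Event table is missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  count_cols <- intersect(
    c("n_ch1_only", "n_ch2_only", "n_double", "n_neither", "n_noise", "total_events"),
    names(data)
  )
  for (col in setdiff(count_cols, c("n_neither", "n_noise"))) {
    bad <- which(is.na(data[[col]]))
    if (length(bad)) {
      abort(sprintf("Missing (NA) count in column %s at row(s) %s.",
                    col, paste(head(bad, 5), collapse = ", ")))
    }
  }
  for (col in count_cols) {
    bad <- which(!is.na(data[[col]]) & data[[col]] < 0)
    if (length(bad)) {
      abort(sprintf("Negative count in column %s at row(s) %s.",
                    col, paste(head(bad, 5), collapse = ", ")))
    }
  }
  n_neither <- if ("n_neither" %in% names(data)) tidyr::replace_na(data$n_neither, 0) else 0
  n_noise <- if ("n_noise" %in% names(data)) tidyr::replace_na(data$n_noise, 0) else 0
  total <- data$n_ch1_only + data$n_ch2_only + data$n_double + n_neither + n_noise
  bad <- which(total != data$total_events)
  if (length(bad)) {
    abort(sprintf("Class counts do not sum to total_events at row(s) %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if ("dilution_factor" %in% names(data)) {
    bad <- which(!is.na(data$dilution_factor) & data$dilution_factor < 1)
    if (length(bad)) {
      abort(sprintf("dilution_factor < 1 at row(s) %s.", paste(head(bad, 5), collapse = ", ")))
    }
  }
  invisible(data)
}

#' Read and write pipeline tables
#'
#' `read_event_table()` reads a gated event-count table and validates its
#' schema; `read_trajectories()` reads frequency/abundance trajectories and
#' checks that times are strictly increasing within each series and
#' frequencies lie in \[0, 1\]; `write_table()` writes any result tibble with
#' embedded metadata comment lines (seed, config hash, package version).
#' `write_corrected()` and `write_results()` are aliases of `write_table()`
#' kept for pipeline readability. Round trips are loss-less on valid tables.
#'
#' @param path File path (CSV, UTF-8, header row; `#` lines are metadata).
#' @param data Data frame to write.
#' @param meta Optional named list embedded as `# key: value` lines; a
#'   `config_hash` over `meta` itself is always added.
#' @return Read functions return validated tibbles; write functions return
#'   `path` invisibly.
#' @export
read_event_table <- function(path) {
  data <- read_csv_quiet(path)
  validate_event_table(data)
  data
}

#' @rdname read_event_table
#' @export
read_trajectories <- function(path) {
  data <- read_csv_quiet(path)
  if (!"time" %in% names(data) && "cycle" %in% names(data)) data$time <- data$cycle
  if (!"time" %in% names(data) && "time_h" %in% names(data)) data$time <- data$time_h
  need <- c("time", "f")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("Trajectory table is missing columns: ", paste(missing, collapse = ", ")))
  }
  bad <- which(data$f < 0 | data$f > 1)
  if (length(bad)) {
    abort(sprintf("Frequency outside [0, 1] at row(s) %s.", paste(head(bad, 5), collapse = ", ")))
  }
  keys <- intersect(c("replicate_id", "replicate", "condition", "strain_id"), names(data))
  grouped <- if (length(keys)) dplyr::group_by(data, dplyr::across(dplyr::all_of(keys))) else data
  ok <- dplyr::summarise(grouped, ok = all(diff(.data$time) > 0), .groups = "drop")
  if (!all(ok$ok)) abort("Times must be strictly increasing within each series.")
  data
}

#' @rdname read_event_table
#' @export
write_table <- function(data, path, meta = list()) {
  meta$package_version <- as.character(utils::packageVersion("cytocompete"))
  meta$config_hash <- rlang::hash(meta)
  header <- sprintf("# %s: %s", names(meta), vapply(meta, format, character(1)))
  body <- readr::format_csv(data)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname read_event_table
#' @export
write_corrected <- write_table

#' @rdname read_event_table
#' @export
write_results <- write_table

read_csv_quiet <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Read and write a flat key-value manifest
#'
#' Fixture manifests record every true generating parameter as `key = value`
#' lines so parameter-recovery tests can compare pipeline output against the
#' truth without re-deriving it.
#'
#' @param params Named list of scalars.
#' @param path File path.
#' @return `read_manifest()`: named list with numeric values converted;
#'   `write_manifest()`: `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  stopifnot(length(names(params)) == length(params))
  lines <- sprintf("%s = %s", names(params),
                   vapply(params, function(x) paste(format(x, digits = 15), collapse = ","),
                          character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(x) {
    vals <- strsplit(x[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (any(is.na(num))) vals else num
  })
  setNames(out, vapply(kv, `[[`, character(1), 1))
}
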