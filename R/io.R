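# Plain-text file formats. All files are whitespace-delimited with
# '#'-prefixed comment/declaration lines. Writers declare the row count
# ("# n_rows: N") so readers can reject silently-truncated files, and every
# writer's output is parsed identically by its own reader (round-trip
# property, tested).

# '#' lines of the form "# key: value" become declarations
read_text_table <- function(path, what = "file") {
  if (!file.exists(path)) stop(what, " not found: ", path)
  lines <- readLines(path, warn = FALSE)
  decl <- list()
  rows <- list()
  first_bad <- NA_integer_
  extra_cols <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
      if (length(m) == 3) decl[[m[2]]] <- m[3]
      next
    }
    fields <- strsplit(ln, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    # literal NaN/Inf parse fine; only genuinely non-numeric fields give NA
    if (any(is.na(vals) & !is.nan(vals))) {
      if (is.na(first_bad)) first_bad <- i
      next
    }
    if (length(vals) > 2) extra_cols <- TRUE
    rows[[length(rows) + 1]] <- vals
  }
  if (length(rows) == 0)
    stop(sprintf("%s %s: no parseable data rows%s", what, path,
                 if (!is.na(first_bad))
                   sprintf(" (first failing line: %d)", first_bad) else ""))
  ncol <- max(lengths(rows))
  mat <- t(vapply(rows, function(r) c(r, rep(NA_real_, ncol - length(r))),
                  numeric(ncol)))
  if (!is.null(decl$n_rows) && as.integer(decl$n_rows) != nrow(mat))
    stop(sprintf("%s %s: declared n_rows = %s but %d rows found (truncated?)",
                 what, path, decl$n_rows, nrow(mat)))
  list(data = mat, decl = decl, extra_cols = extra_cols)
}

#' Read / write a reaction-coordinate timeseries
#'
#' Two-column whitespace-delimited text: time (ps) and z (Angstrom), with
#' '#' comment lines. Extra columns are ignored with a notice. The writer
#' declares the save interval and row count; the reader infers the save
#' interval from the time column when not declared.
#'
#' @param path file path.
#' @return `read_timeseries` returns a `time_series` (no burn-in flag and no
#'   seed: file-loaded data are taken as production samples).
#' @export
read_timeseries <- function(path) {
  tab <- read_text_table(path, "timeseries")
  if (ncol(tab$data) < 2)
    stop("timeseries ", path, ": expected two columns (time, value)")
  if (tab$extra_cols)
    message("timeseries ", path, ": extra columns ignored")
  t <- tab$data[, 1]; z <- tab$data[, 2]
  dt <- if (!is.null(tab$decl$save_interval_ps))
    as.numeric(tab$decl$save_interval_ps)
  else if (length(t) >= 2) t[2] - t[1] else NA_real_
  new_time_series(z, save_interval = dt)
}

#' @rdname read_timeseries
#' @param ts a `time_series`.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  dt <- if (is.na(ts$save_interval)) 1 else ts$save_interval
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pmfkd timeseries (time_ps z_A)",
               sprintf("# save_interval_ps: %.17g", dt),
               sprintf("# n_rows: %d", length(ts$z))), con)
  writeLines(sprintf("%.17g %.17g", seq_along(ts$z) * dt, ts$z), con)
  invisible(path)
}

#' Read / write umbrella-window metadata
#'
#' Grossfield-style metadata: one window per line, "path center spring",
#' with mandatory header declarations -- there is no guessing of energy
#' dialects, the classic silent-error source across WHAM tools:
#' \preformatted{
#' # energy_unit: kT            (or kcal/mol)
#' # bias_convention: half-k    (or full-k)
#' # temperature_K: 298.15      (required for kcal/mol)
#' win01.dat 8.0 4.0
#' }
#' Spring constants are converted on load to the internal convention,
#' E = 1/2 k (z - z0)^2 with k in kT/A^2: a kcal/mol declaration divides by
#' kB*T (kB = 0.0019872 kcal/mol/K), and a full-k declaration (files whose
#' bias was E = k (z - z0)^2) doubles k so the bias energy is preserved.
#' Timeseries paths resolve relative to the metadata file.
#'
#' @param path metadata file path.
#' @return list with `windows` (list of `umbrella_window`), `series` (list of
#'   `time_series` with windows attached), and the declarations.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  decl <- list()
  windows <- list(); series <- list(); paths <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
      if (length(m) == 3) decl[[m[2]]] <- m[3]
      next
    }
    fields <- strsplit(ln, "\\s+")[[1]]
    if (length(fields) < 3)
      stop("metadata line ", i, ": expected 'path center spring'")
    num <- suppressWarnings(as.numeric(fields[2:3]))
    if (anyNA(num))
      stop("metadata line ", i, ": non-numeric center/spring")
    paths <- c(paths, fields[1])
    windows[[length(windows) + 1]] <- list(center = num[1], spring = num[2])
  }
  if (length(windows) == 0) stop("metadata ", path, ": no window records")
  if (anyDuplicated(paths)) stop("metadata ", path, ": duplicate timeseries paths")
  unit <- decl$energy_unit
  conv <- decl$bias_convention
  if (is.null(unit) || is.null(conv))
    stop("metadata ", path, ": energy_unit and bias_convention declarations ",
         "are mandatory")
  if (!unit %in% c("kT", "kcal/mol"))
    stop("unknown energy_unit '", unit, "' (use kT or kcal/mol)")
  if (!conv %in% c("half-k", "full-k"))
    stop("unknown bias_convention '", conv, "' (use half-k or full-k)")
  Tk <- as.numeric(decl$temperature_K %||% 298.15)
  if (unit == "kcal/mol" && is.null(decl$temperature_K))
    message("metadata ", path, ": kcal/mol with no temperature_K; ",
            "assuming 298.15 K")
  scale <- (if (unit == "kcal/mol") 1 / (KB_KCAL * Tk) else 1) *
    (if (conv == "full-k") 2 else 1)
  base <- dirname(path)
  for (i in seq_along(windows)) {
    w <- umbrella_window(windows[[i]]$center, windows[[i]]$spring * scale,
                         label = basename(paths[i]))
    windows[[i]] <- w
    fp <- if (grepl("^(/|[A-Za-z]:)", paths[i])) paths[i]
          else file.path(base, paths[i])
    if (!file.exists(fp))
      stop("metadata ", path, " references missing timeseries: ", paths[i])
    ts <- read_timeseries(fp)
    ts$window <- w
    series[[i]] <- ts
  }
  list(windows = windows, series = series, decl = decl, temperature = Tk)
}

#' Write a simulated window set as timeseries + metadata files
#'
#' @param series list of `time_series` with windows (e.g. from
#'   [generate_window_set()]). Burn-in samples are dropped on write: files
#'   contain production data only.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix for the per-window files.
#' @param temperature temperature in K recorded in the metadata.
#' @return the metadata file path.
#' @export
write_window_set <- function(series, dir, prefix = "window",
                             temperature = 298.15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%02d.dat", prefix, seq_along(series))
  for (i in seq_along(series)) {
    ts <- series[[i]]
    out <- new_time_series(production_samples(ts), ts$save_interval,
                           window = ts$window)
    write_timeseries(out, file.path(dir, files[i]))
  }
  meta <- file.path(dir, paste0(prefix, "_metadata.txt"))
  con <- file(meta, "w")
  on.exit(close(con))
  writeLines(c("# pmfkd window metadata (path center_A spring)",
               "# energy_unit: kT",
               "# bias_convention: half-k",
               sprintf("# temperature_K: %.17g", temperature)), con)
  for (i in seq_along(series)) {
    w <- series[[i]]$window
    writeLines(sprintf("%s %.17g %.17g", files[i], w$center, w$spring), con)
  }
  invisible(meta)
}

#' Read / write a PMF table
#'
#' Three-column text (z_A, W_kT, sigma_kT); sigma is written as NaN when no
#' uncertainty is attached and +Inf marks unsampled bins.
#'
#' @param path file path.
#' @export
read_pmf <- function(path) {
  tab <- read_text_table(path, "PMF table")
  if (ncol(tab$data) < 2) stop("PMF table ", path, ": expected >= 2 columns")
  sigma <- if (ncol(tab$data) >= 3 && !all(is.nan(tab$data[, 3])))
    tab$data[, 3] else NULL
  new_pmf_profile(tab$data[, 1], tab$data[, 2], sigma,
                  convention = tab$decl$zero_convention %||% "none",
                  temperature = as.numeric(tab$decl$temperature_K %||% 298.15))
}

#' @rdname read_pmf
#' @param p a `pmf_profile`.
#' @export
write_pmf <- function(p, path) {
  stopifnot(inherits(p, "pmf_profile"))
  sigma <- p$sigma %||% rep(NaN, length(p$z))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pmfkd PMF table (z_A W_kT sigma_kT)",
               sprintf("# zero_convention: %s", p$convention),
               sprintf("# temperature_K: %.17g", p$temperature),
               sprintf("# n_rows: %d", length(p$z))), con)
  writeLines(sprintf("%.10g %.10g %.10g", p$z, p$W, sigma), con)
  invisible(path)
}

#' Read / write a tabulated potential
#'
#' Two-column text (z_A, W_kT) with '#' comments; the grid must be strictly
#' increasing.
#'
#' @param path file path.
#' @export
read_potential_table <- function(path) {
  tab <- read_text_table(path, "potential table")
  if (ncol(tab$data) < 2)
    stop("potential table ", path, ": expected two columns (z, W)")
  tabulated_potential(tab$data[, 1], tab$data[, 2])
}

#' @rdname read_potential_table
#' @param p a tabulated `potential_1d`.
#' @export
write_potential_table <- function(p, path) {
  stopifnot(inherits(p, "potential_1d"), p$kind == "tabulated")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# pmfkd tabulated potential (z_A W_kT)",
               sprintf("# n_rows: %d", length(p$params$z))), con)
  writeLines(sprintf("%.17g %.17g", p$params$z, p$params$W), con)
  invisible(path)
}
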