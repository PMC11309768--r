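#' Residue identifier
#'
#' Residues are indexed in the full-length protein numbering (for TRBP2,
#' 1-366); a one-letter amino-acid code is optional.
#'
#' @param number integer residue index (>= 1).
#' @param name optional one-letter amino-acid code.
#' @return An object of class `residue_id`.
#' @export
residue_id <- function(number, name = NA_character_) {
  number <- as.integer(number)
  if (is.na(number) || number < 1) stop("residue number must be >= 1")
  structure(list(number = number, name = name), class = "residue_id")
}

#' Parse a residue row label such as "G162" or "G162N-H"
#'
#' Accepts plain numbers, one-letter-code + number, and peak-list style
#' labels with a trailing atom specification (anything after the number is
#' ignored).
#'
#' @param label character scalar.
#' @return A [residue_id()].
#' @export
parse_residue_label <- function(label) {
  label <- trimws(label)
  m <- regmatches(label, regexec("^([A-Za-z]?)([0-9]+)", label))[[1]]
  if (length(m) == 0 || m[3] == "")
    stop(sprintf("cannot parse residue label '%s'", label))
  residue_id(as.integer(m[3]), if (nzchar(m[2])) toupper(m[2]) else NA_character_)
}

#' Core-window membership test
#'
#' Pure predicate for whether a residue lies inside a configured core window
#' (default: the dsRBD2 core, residues 159-227).
#'
#' @param number residue number(s).
#' @param window length-2 numeric, inclusive bounds.
#' @return logical vector.
#' @export
is_core_residue <- function(number, window = c(159, 227)) {
  number >= window[1] & number <= window[2]
}

#' Relaxation delay schedule
#'
#' An ordered set of relaxation delays with flags marking delays acquired in
#' duplicate. The total number of acquired points is
#' `length(delays) + sum(duplicate_flags)`.
#'
#' @param delays numeric vector of delays, seconds, all >= 0.
#' @param duplicate_flags logical vector, same length, marking delays
#'   acquired twice.
#' @return An object of class `delay_schedule`.
#' @export
delay_schedule <- function(delays, duplicate_flags = rep(FALSE, length(delays))) {
  stopifnot(is.numeric(delays), length(delays) >= 1,
            all(is.finite(delays)), all(delays >= 0),
            length(duplicate_flags) == length(delays))
  structure(list(delays = as.numeric(delays),
                 duplicate_flags = as.logical(duplicate_flags)),
            class = "delay_schedule")
}

#' Number of acquired points implied by a schedule
#' @param schedule a [delay_schedule()].
#' @return integer count.
#' @export
n_points <- function(schedule) {
  length(schedule$delays) + sum(schedule$duplicate_flags)
}

#' Expand a schedule into acquired-point order
#'
#' Canonical column order for intensity tables: delays in listed order, with
#' each duplicate-flagged delay contributing two consecutive points. The
#' second copy of a pair carries the same `pair` index as the first.
#'
#' @param schedule a [delay_schedule()].
#' @return data.frame with columns `time` (s), `is_duplicate_copy`, `pair`
#'   (pair index for duplicated delays, NA otherwise).
#' @export
expand_schedule <- function(schedule) {
  times <- c(); dup <- c(); pair <- c()
  k <- 0L
  for (i in seq_along(schedule$delays)) {
    t <- schedule$delays[i]
    if (schedule$duplicate_flags[i]) {
      k <- k + 1L
      times <- c(times, t, t); dup <- c(dup, FALSE, TRUE); pair <- c(pair, k, k)
    } else {
      times <- c(times, t); dup <- c(dup, FALSE); pair <- c(pair, NA_integer_)
    }
  }
  data.frame(time = times, is_duplicate_copy = dup, pair = pair)
}

#' Parse a delay schedule from text
#'
#' The text form lists delays in milliseconds, comma- or whitespace-
#' separated, with an optional trailing `*` marking a delay acquired in
#' duplicate -- e.g. the inversion-recovery schedule
#' `"10, 30*, 50, 100, 200, 300, 450*, 600"`.
#'
#' @param text character scalar.
#' @return A [delay_schedule()] with delays converted to seconds.
#' @export
read_delay_schedule <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  tokens <- strsplit(trimws(text), "[,[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) stop("empty delay schedule")
  starred <- grepl("\\*$", tokens)
  raw <- sub("\\*$", "", tokens)
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- tokens[which(is.na(vals))[1]]
    stop(sprintf("non-numeric delay token '%s'", bad))
  }
  delay_schedule(vals / 1000, starred)
}

#' Format a delay schedule back to its text form (ms, `*` = duplicate)
#' @param schedule a [delay_schedule()].
#' @return character scalar.
#' @export
format_delay_schedule <- function(schedule) {
  ms <- schedule$delays * 1000
  paste0(format(ms, trim = TRUE, scientific = FALSE, drop0trailing = TRUE),
         ifelse(schedule$duplicate_flags, "*", ""),
         collapse = ", ")
}

#' Per-residue intensity series
#'
#' Peak heights over the acquired points of a [delay_schedule()] (in
#' [expand_schedule()] order). Missing points are `NA` (e.g. residues
#' broadened beyond detection at some delays).
#'
#' @param residue a [residue_id()].
#' @param schedule a [delay_schedule()].
#' @param heights numeric, one per acquired point (NA allowed).
#' @param noise_sigma optional non-negative intensity noise estimate.
#' @return An object of class `intensity_series`.
#' @export
intensity_series <- function(residue, schedule, heights, noise_sigma = NULL) {
  stopifnot(inherits(residue, "residue_id"), inherits(schedule, "delay_schedule"))
  if (length(heights) != n_points(schedule))
    stop(sprintf("residue %d: %d heights for %d acquired points",
                 residue$number, length(heights), n_points(schedule)))
  if (any(is.infinite(heights))) stop("heights must be finite or NA")
  if (!is.null(noise_sigma)) stopifnot(noise_sigma >= 0)
  structure(list(residue = residue, schedule = schedule,
                 heights = as.numeric(heights), noise_sigma = noise_sigma),
            class = "intensity_series")
}

#' Observed (time, height) points of a series, NA dropped
#' @param series an [intensity_series()].
#' @return data.frame with columns `time`, `height`.
#' @export
series_points <- function(series) {
  ex <- expand_schedule(series$schedule)
  keep <- !is.na(series$heights)
  data.frame(time = ex$time[keep], height = series$heights[keep])
}

#' Read an intensity table
#'
#' Rows are residues, columns the acquired points of `schedule` in
#' [expand_schedule()] order. Two dialects are supported: `"csv"` (one
#' header line; first column the residue label) and `"peak-height-export"`
#' (whitespace-delimited with an `Assignment` first column, as produced by
#' common assignment tools). Empty cells load as missing points.
#'
#' @param path file path.
#' @param schedule a [delay_schedule()] describing the columns.
#' @param dialect `"csv"` or `"peak-height-export"`.
#' @return named list of [intensity_series()], one per residue.
#' @export
read_intensity_table <- function(path, schedule,
                                 dialect = c("csv", "peak-height-export")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            colClasses = "character", strip.white = TRUE)
    if (tolower(names(df)[1]) != "assignment")
      stop("peak-height-export dialect requires an 'Assignment' first column")
  }
  np <- n_points(schedule)
  if (ncol(df) - 1 != np)
    stop(sprintf("table has %d data columns but the schedule implies %d points",
                 ncol(df) - 1, np))
  labels <- df[[1]]
  out <- list()
  for (i in seq_len(nrow(df))) {
    rid <- parse_residue_label(labels[i])
    key <- as.character(rid$number)
    if (!is.null(out[[key]]))
      stop(sprintf("duplicate rows for residue %d", rid$number))
    cells <- as.character(df[i, -1])
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & nzchar(cells) & !is.na(cells))
    if (length(bad))
      stop(sprintf("residue %d: non-numeric height '%s'", rid$number, cells[bad[1]]))
    out[[key]] <- intensity_series(rid, schedule, vals)
  }
  if (length(out) != nrow(df)) stop("row count changed while parsing") # never silent
  out
}

.rate_kinds <- c("R1", "R2", "nOe", "R1rho", "R2rho", "R2eff")

#' Per-residue relaxation observable table
#'
#' Validating constructor for the central tabular container: one row per
#' (residue, observable kind, field, state, condition). `cond` carries the
#' HSn label for rotating-frame rates or the CPMG frequency (Hz, as a
#' string) for R2eff rows, and is NA otherwise.
#'
#' @param df data.frame with columns `residue` (integer), `kind` (one of
#'   R1, R2, nOe, R1rho, R2rho, R2eff), `value`, `sigma` (>= 0), `field`
#'   (MHz), `state` ("apo" or "bound"), and optionally `cond`.
#' @return the validated data.frame with class `rate_table`.
#' @export
rate_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"cond" %in% names(df)) df$cond <- NA_character_
  need <- c("residue", "kind", "value", "sigma", "field", "state", "cond")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("rate table missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  bad <- setdiff(unique(df$kind), .rate_kinds)
  if (length(bad)) stop("unknown observable kind: ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$value))) stop("rate values must be finite")
  if (any(df$sigma < 0, na.rm = TRUE)) stop("uncertainties must be >= 0")
  if (!all(df$state %in% c("apo", "bound")))
    stop("state must be 'apo' or 'bound'")
  key <- paste(df$residue, df$kind, df$field, df$state, df$cond, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (residue, kind, field, state, cond) records")
  df$residue <- as.integer(df$residue)
  class(df) <- c("rate_table", "data.frame")
  df
}

#' Write a rate table to CSV (lossless to ~1e-15 relative)
#' @param table a [rate_table()].
#' @param path output file.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "rate_table"))
  out <- as.data.frame(table)
  for (col in c("value", "sigma", "field"))
    out[[col]] <- format(out[[col]], digits = 17, trim = TRUE, scientific = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a rate table written by [write_rate_table()]
#' @param path input file.
#' @return a [rate_table()].
#' @export
read_rate_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = c(cond = "character"), na.strings = "")
  rate_table(df)
}

#' Select rows of a rate table
#' @param table a [rate_table()].
#' @param kind,field,state,cond,window optional filters; `window` is an
#'   inclusive residue-number range.
#' @return filtered `rate_table`.
#' @export
filter_rates <- function(table, kind = NULL, field = NULL, state = NULL,
                         cond = NULL, window = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(kind)) keep <- keep & table$kind %in% kind
  if (!is.null(field)) keep <- keep & table$field %in% field
  if (!is.null(state)) keep <- keep & table$state %in% state
  if (!is.null(cond)) keep <- keep & table$cond %in% cond
  if (!is.null(window)) keep <- keep & is_core_residue(table$residue, window)
  out <- table[keep, , drop = FALSE]
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Read a flat key/value run configuration
#'
#' One flat YAML document covering field strengths, core windows, physical
#' constants and seeds. Unknown keys are kept; missing keys fall back to
#' package defaults.
#'
#' @param path YAML file, or NULL for defaults only.
#' @return named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    fields_mhz = c(600, 800),
    core_window = c(159, 227),
    rNH = 1.02e-10, dsigmaN = -172e-6,
    gammaH = 2.6752218744e8, gammaN = -2.7126e7,
    mc_n = 500, seed = 1,
    rex_thresholds = c(1, 2),
    kex_bins = c(5000, 50000),
    noe_rigid_cutoff = 0.65
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}

# run restoring the caller's RNG state afterwards; seed = NULL leaves RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}
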