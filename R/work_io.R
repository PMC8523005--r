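#' Read a GROMACS-style dhdl.xvg file
#'
#' Parses the xvg dialect written by GROMACS for alchemical runs: lines
#' starting with `#` (comments) or `@` (grace directives) are metadata;
#' remaining lines are whitespace-separated numeric columns. Column 1 is time
#' (ns), column 2 is dH/dlambda. If a third column lies within [0, 1] it is
#' taken as the lambda value of each frame; otherwise lambda is derived later
#' from a linear schedule (see [work_from_dhdl()]).
#'
#' Energies are stored internally in kcal/mol; GROMACS writes kJ/mol, so the
#' default `unit` divides dH/dlambda by 4.184.
#'
#' @param path file path.
#' @param unit unit of the energy column in the file: `"kJ/mol"` (GROMACS
#'   native, default) or `"kcal/mol"`.
#' @return an object of class `dhdl_series`: a list with `time` (ns), `dhdl`
#'   (kcal/mol per unit lambda), `lam` (lambda values or `NULL`),
#'   `source_units`, and the column mapping used.
#' @export
read_xvg <- function(path, unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*[#@]", lines) | !nzchar(trimws(lines))
  data_idx <- which(!is_meta)
  if (length(data_idx) == 0L) stop("no data rows in ", path,
                                   " (only comments/directives)")
  rows <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncol <- length(rows[[1L]])
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(vals, function(v) anyNA(v) | length(v) != ncol,
                      logical(1)))
  if (length(bad))
    stop("non-numeric or ragged data row at line ", data_idx[bad[1L]],
         " of ", path)
  m <- do.call(rbind, vals)
  if (nrow(m) < 2L) stop("insufficient data in ", path, ": need >= 2 rows")
  if (ncol < 2L) stop("need at least time and dhdl columns in ", path)
  time <- m[, 1L]
  dhdl <- m[, 2L]
  lam <- NULL
  mapping <- c(time = 1L, dhdl = 2L)
  if (ncol >= 3L && all(m[, 3L] >= 0 & m[, 3L] <= 1)) {
    lam <- m[, 3L]
    mapping <- c(mapping, lam = 3L)
  }
  if (unit == "kJ/mol") dhdl <- .kj_to_kcal(dhdl)
  dhdl_series(time = time, dhdl = dhdl, lam = lam, source_units = unit,
              mapping = mapping)
}

#' Construct a dhdl time series
#'
#' @param time time stamps in ns; must be non-decreasing. Duplicate stamps are
#'   dropped (first occurrence kept) with a warning.
#' @param dhdl dH/dlambda values in kcal/mol per unit lambda.
#' @param lam optional explicit lambda column in [0, 1].
#' @param source_units unit the data came from (bookkeeping only; `dhdl` is
#'   always kcal/mol here).
#' @param mapping named integer vector recording source columns.
#' @return an object of class `dhdl_series`.
#' @export
dhdl_series <- function(time, dhdl, lam = NULL, source_units = "kcal/mol",
                        mapping = NULL) {
  stopifnot(length(time) == length(dhdl))
  if (!is.null(lam)) {
    stopifnot(length(lam) == length(time))
    if (any(lam < 0 | lam > 1)) stop("'lam' values must lie in [0, 1]")
  }
  if (length(time) < 2L) stop("insufficient data: need >= 2 rows")
  if (is.unsorted(time)) stop("'time' must be non-decreasing")
  dup <- duplicated(time)
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicate time stamp(s), keeping first")
    time <- time[!dup]; dhdl <- dhdl[!dup]
    if (!is.null(lam)) lam <- lam[!dup]
  }
  if (length(time) < 2L) stop("insufficient data after deduplication")
  if (anyNA(dhdl)) stop("NaN/NA in dhdl data")
  structure(list(time = time, dhdl = dhdl, lam = lam,
                 source_units = source_units, mapping = mapping),
            class = "dhdl_series")
}

#' @export
print.dhdl_series <- function(x, ...) {
  cat(sprintf("<dhdl_series> %d frames, t = [%g, %g] ns, %s lambda column\n",
              length(x$time), min(x$time), max(x$time),
              if (is.null(x$lam)) "no" else "explicit"))
  invisible(x)
}

#' Work of a nonequilibrium trajectory from its dhdl series
#'
#' Integrates dH/dlambda over the lambda grid by the trapezoidal rule and
#' applies the direction sign: `W = sign * integral of dH/dlambda dlambda`,
#' with `sign = +1` for the forward (A to B) and `-1` for the reverse (B to A)
#' process. Lambda is taken from the explicit column when present, otherwise
#' from a linear schedule `lambda(t) = (t - t0) / (t_end - t0)`.
#'
#' @param series a [dhdl_series].
#' @param direction_sign `+1` (forward) or `-1` (reverse).
#' @param schedule `"linear"` (default; only used when the series carries no
#'   explicit lambda column) or a function mapping time to lambda in [0, 1].
#' @return work in kcal/mol.
#' @export
#' @examples
#' s <- dhdl_series(time = seq(0, 1, length.out = 1001),
#'                  dhdl = 2 * seq(0, 1, length.out = 1001))
#' work_from_dhdl(s, +1) # integral of 2*lambda = 1
work_from_dhdl <- function(series, direction_sign = 1, schedule = "linear") {
  stopifnot(inherits(series, "dhdl_series"))
  if (!direction_sign %in% c(-1, 1))
    stop("'direction_sign' must be +1 or -1")
  lam <- series$lam
  if (is.null(lam)) {
    if (is.function(schedule)) {
      lam <- schedule(series$time)
      if (any(lam < 0 | lam > 1)) stop("schedule maps outside [0, 1]")
    } else if (identical(schedule, "linear")) {
      t0 <- series$time[1L]
      t1 <- series$time[length(series$time)]
      lam <- (series$time - t0) / (t1 - t0)
    } else stop("unknown schedule")
  }
  if (is.unsorted(lam)) stop("lambda not monotone under the given schedule")
  if (anyNA(series$dhdl)) stop("NaN in dhdl")
  dl <- diff(lam)
  w <- sum(dl * (utils::head(series$dhdl, -1) + utils::tail(series$dhdl, -1)) / 2)
  direction_sign * w
}

.direction_tokens <- c(forward = "forward", reverse = "reverse")

#' Read a plain work table into work sets
#'
#' The table is a UTF-8 TSV with header columns `direction`, `tau_ns`,
#' `k_rstr`, `temperature_K`, `work_kcal` and one work value per row. Rows are
#' grouped by (direction, tau_ns, k_rstr, temperature_K) into one [work_set]
#' per condition and direction.
#'
#' @param path file path.
#' @return a list of [work_set] objects (possibly empty).
#' @seealso [write_work_table()]
#' @export
read_work_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("direction", "tau_ns", "k_rstr", "temperature_K", "work_kcal")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("work table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  bad <- setdiff(unique(df$direction), .direction_tokens)
  if (length(bad))
    stop("unknown direction token(s): ", paste(bad, collapse = ", "))
  key <- interaction(df$direction, df$tau_ns, df$k_rstr, df$temperature_K,
                     drop = TRUE)
  lapply(split(df, key), function(g)
    work_set(g$work_kcal, direction = g$direction[1L], tau_ns = g$tau_ns[1L],
             k_rstr = g$k_rstr[1L], temperature_K = g$temperature_K[1L]))
}

#' Write work sets to a plain work table
#'
#' Values are written with 12 significant digits so that a write/read
#' round-trip is bit-stable at that precision.
#'
#' @param worksets a [work_set] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_work_table <- function(worksets, path) {
  if (is_work_set(worksets)) worksets <- list(worksets)
  rows <- lapply(worksets, function(ws)
    data.frame(direction = ws$direction, tau_ns = ws$tau_ns,
               k_rstr = ws$k_rstr, temperature_K = ws$temperature_K,
               work_kcal = ws$works))
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(direction = character(), tau_ns = numeric(),
                     k_rstr = numeric(), temperature_K = numeric(),
                     work_kcal = numeric())
  df$work_kcal <- formatC(df$work_kcal, digits = 12, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
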