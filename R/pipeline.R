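# End-to-end orchestration: config-driven analysis over a grid of switching
# times and restraint strengths, producing estimate / correction / ABFE
# tables plus a JSON bundle and run log.

#' Read a run configuration (YAML or JSON)
#'
#' The configuration lists the work inputs, the estimators, the correction
#' protocol and the bootstrap settings. Recognized top-level keys:
#' \describe{
#'   \item{input}{`work_table` (path to a TSV readable by
#'     [read_work_table()]) or `xvg_manifest` (path to a TSV with columns
#'     `path`, `direction`, `tau_ns`, `k_rstr`, `temperature_K`; each xvg is
#'     integrated by [work_from_dhdl()]). Optionally `xvg_unit`.}
#'   \item{estimators}{subset of `bar`, `jarzynski`, `gaussian`,
#'     `jarzynski_mean`, `em` (default: all).}
#'   \item{protocol}{`"boresch"`, `"volume_symmetry"` or `"none"`.}
#'   \item{restraint}{for the boresch protocol: `d1_A`, `theta2_deg` or
#'     `theta2_rad`, `theta3_deg` or `theta3_rad` (k and T come from each
#'     condition). Alternatively a fixed `dAr` constant.}
#'   \item{volume}{for the volume_symmetry protocol: `v_site_A3` or a fixed
#'     `dG_vol`; optional `n_poses` for the symmetry term, or a fixed
#'     `TdS_sym`.}
#'   \item{bootstrap_n, seed, primary, n_g}{analysis settings; `primary`
#'     names the estimator assembled into the ABFE table (default `bar`).}
#' }
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("config must be YAML or JSON")
  run_config(cfg)
}

#' Validate a run-configuration list
#'
#' @param cfg a named list with the keys documented in [read_run_config()].
#' @return the validated list, classed `run_config`.
#' @export
run_config <- function(cfg) {
  cfg$estimators <- if (is.null(cfg$estimators))
    c("bar", "jarzynski", "gaussian", "jarzynski_mean", "em")
  else match.arg(tolower(cfg$estimators),
                 c("bar", "jarzynski", "gaussian", "jarzynski_mean", "em"),
                 several.ok = TRUE)
  if (length(cfg$estimators) < 1L) stop("need at least one estimator")
  cfg$protocol <- if (is.null(cfg$protocol)) "none"
  else match.arg(tolower(cfg$protocol),
                 c("boresch", "volume_symmetry", "none"))
  if (cfg$protocol == "boresch" && is.null(cfg$restraint))
    stop("boresch protocol needs a 'restraint' block")
  if (cfg$protocol == "volume_symmetry" && is.null(cfg$volume))
    stop("volume_symmetry protocol needs a 'volume' block")
  if (is.null(cfg$bootstrap_n)) cfg$bootstrap_n <- 1000L
  if (is.null(cfg$primary)) cfg$primary <- "bar"
  if (is.null(cfg$n_g)) cfg$n_g <- 2L
  structure(cfg, class = "run_config")
}

# restraint geometry for one condition from the config restraint block
.geometry_from_config <- function(rb, k_rstr, temperature_K) {
  theta2 <- if (!is.null(rb$theta2_rad)) rb$theta2_rad
            else rb$theta2_deg * pi / 180
  theta3 <- if (!is.null(rb$theta3_rad)) rb$theta3_rad
            else rb$theta3_deg * pi / 180
  restraint_geometry(rb$d1_A, theta2, theta3, k_rstr,
                     temperature_K = temperature_K)
}

.load_worksets <- function(cfg) {
  inp <- cfg$input
  if (!is.null(inp$work_table)) return(read_work_table(inp$work_table))
  if (!is.null(inp$xvg_manifest)) {
    man <- utils::read.table(inp$xvg_manifest, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    required <- c("path", "direction", "tau_ns", "k_rstr", "temperature_K")
    missing <- setdiff(required, names(man))
    if (length(missing))
      stop("xvg manifest is missing column(s): ",
           paste(missing, collapse = ", "))
    unit <- if (is.null(inp$xvg_unit)) "kJ/mol" else inp$xvg_unit
    base <- dirname(inp$xvg_manifest)
    man$work_kcal <- vapply(seq_len(nrow(man)), function(i) {
      p <- man$path[i]
      if (!file.exists(p)) p <- file.path(base, man$path[i])
      work_from_dhdl(read_xvg(p, unit = unit),
                     direction_sign = if (man$direction[i] == "forward") 1
                                      else -1)
    }, numeric(1))
    key <- interaction(man$direction, man$tau_ns, man$k_rstr,
                       man$temperature_K, drop = TRUE)
    return(lapply(split(man, key), function(g)
      work_set(g$work_kcal, direction = g$direction[1L],
               tau_ns = g$tau_ns[1L], k_rstr = g$k_rstr[1L],
               temperature_K = g$temperature_K[1L])))
  }
  stop("config 'input' must give 'work_table' or 'xvg_manifest'")
}

.fmt2 <- function(x) ifelse(is.finite(x), sprintf("%.2f", x), "n/a")

#' Run a configured analysis over all conditions
#'
#' Groups the input work sets into (tau, K, T) conditions, fits [neqfe()]
#' per condition, applies the configured correction protocol, and writes
#' `estimates.tsv`, `corrections.tsv`, `abfe.tsv` (values at 2 decimals,
#' gated-out estimates rendered `n/a`), a full-precision `bundle.json` and a
#' `run.log` into `out_dir`. Two runs with the same configuration and seed
#' produce byte-identical TSV output. Conditions with fewer than 2 work
#' values are skipped with a warning; an estimator failure is recorded for
#' its cell and the run continues. Estimate tables are reported on the
#' binding convention.
#'
#' @param cfg a [run_config], a config list, or a path to a YAML/JSON file.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param seed overrides `cfg$seed` when given.
#' @return (invisibly) an object of class `neqfe_run`: a list with
#'   `estimates`, `corrections`, `abfe` data.frames, the `fits`, the config
#'   and the seed.
#' @export
run_analysis <- function(cfg, out_dir = NULL, seed = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  worksets <- .load_worksets(cfg)

  cond_key <- vapply(worksets, function(ws)
    sprintf("%g|%g|%g", ws$tau_ns, ws$k_rstr, ws$temperature_K),
    character(1))
  conditions <- unique(cond_key)

  est_rows <- list(); corr_rows <- list(); abfe_rows <- list()
  fits <- list()
  for (ci in seq_along(conditions)) {
    key <- conditions[ci]
    group <- worksets[cond_key == key]
    dirs <- vapply(group, `[[`, character(1), "direction")
    fwd <- group[dirs == "forward"]
    rev <- group[dirs == "reverse"]
    ref <- group[[1L]]
    if ((length(fwd) && length(fwd[[1L]]$works) < 2L) ||
        (length(rev) && length(rev[[1L]]$works) < 2L) ||
        length(fwd) == 0L) {
      warning("condition tau=", ref$tau_ns, " K=", ref$k_rstr,
              " skipped: fewer than 2 work values or no forward set")
      next
    }
    fit <- tryCatch(
      neqfe(fwd[[1L]], if (length(rev)) rev[[1L]] else NULL,
            estimators = cfg$estimators, n_g = cfg$n_g,
            n_boot = cfg$bootstrap_n, seed = seed + ci),
      error = function(e) e)
    if (inherits(fit, "error")) {
      est_rows[[key]] <- data.frame(
        tau_ns = ref$tau_ns, k_rstr = ref$k_rstr, method = "all",
        value = NA_real_, ci95 = NA_real_, applicable = FALSE,
        note = conditionMessage(fit))
      next
    }
    fits[[key]] <- fit
    tab <- estimates_table(fit, convention = "binding")
    est_rows[[key]] <- data.frame(tau_ns = ref$tau_ns, k_rstr = ref$k_rstr,
                                  tab, note = "")

    corr <- switch(cfg$protocol,
      boresch = {
        dAr <- if (!is.null(cfg$restraint$dAr)) cfg$restraint$dAr
               else boresch_correction(.geometry_from_config(
                 cfg$restraint, ref$k_rstr, ref$temperature_K))
        TdS <- if (!is.null(cfg$restraint$TdS_sym)) cfg$restraint$TdS_sym
               else if (!is.null(cfg$restraint$n_poses))
                 symmetry_entropy(cfg$restraint$n_poses, ref$temperature_K)
               else NULL
        correction_set(dAr = dAr, TdS_sym = TdS)
      },
      volume_symmetry = {
        dGv <- if (!is.null(cfg$volume$dG_vol)) cfg$volume$dG_vol
               else volume_correction(cfg$volume$v_site_A3,
                                      ref$temperature_K)
        TdS <- if (!is.null(cfg$volume$TdS_sym)) cfg$volume$TdS_sym
               else if (!is.null(cfg$volume$n_poses))
                 symmetry_entropy(cfg$volume$n_poses, ref$temperature_K)
               else NULL
        correction_set(dG_vol = dGv, TdS_sym = TdS)
      },
      none = correction_set())
    corr_rows[[key]] <- data.frame(
      tau_ns = ref$tau_ns, k_rstr = ref$k_rstr,
      dAr = if (is.null(corr$dAr)) NA_real_ else corr$dAr,
      dG_vol = if (is.null(corr$dG_vol)) NA_real_ else corr$dG_vol,
      TdS_sym = if (is.null(corr$TdS_sym)) NA_real_ else corr$TdS_sym)

    prim <- switch(cfg$primary, bar = "BAR",
                   jarzynski_mean = "JarzynskiMean",
                   jarzynski = "Jarzynski.forward",
                   gaussian = "Gaussian.forward", em = "EM.forward")
    if (!is.null(fit$estimates[[prim]])) {
      abfe <- assemble_abfe(fit$estimates[[prim]], corr,
                            convention = "binding")
      raw_binding <- fe_convention(fit$estimates[[prim]], "binding")
      abfe_rows[[key]] <- data.frame(
        tau_ns = ref$tau_ns, k_rstr = ref$k_rstr, method = prim,
        raw = raw_binding$value,
        corr_total = abfe$value - raw_binding$value,
        abfe = abfe$value, ci95 = abfe$ci95)
    }
  }

  res <- structure(
    list(estimates = do.call(rbind, c(est_rows, list(NULL))),
         corrections = do.call(rbind, c(corr_rows, list(NULL))),
         abfe = do.call(rbind, c(abfe_rows, list(NULL))),
         fits = fits, config = unclass(cfg), seed = seed),
    class = "neqfe_run")
  if (!is.null(out_dir)) .write_run(res, out_dir)
  invisible(res)
}

.write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, fmt_cols, path) {
    if (is.null(df)) df <- data.frame()
    out <- df
    for (cn in intersect(fmt_cols, names(out)))
      out[[cn]] <- .fmt2(out[[cn]])
    if ("applicable" %in% names(out) && "value" %in% names(out))
      out$value[!df$applicable] <- "n/a"
    utils::write.table(out, file.path(out_dir, path), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  wr(res$estimates, c("value", "ci95"), "estimates.tsv")
  wr(res$corrections, c("dAr", "dG_vol", "TdS_sym"), "corrections.tsv")
  wr(res$abfe, c("raw", "corr_total", "abfe", "ci95"), "abfe.tsv")
  cfg_json <- jsonlite::toJSON(res$config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  bundle <- list(estimates = res$estimates, corrections = res$corrections,
                 abfe = res$abfe, seed = res$seed, config = res$config,
                 config_md5 = cfg_hash,
                 package_version = as.character(utils::packageVersion("neqfe")))
  jsonlite::write_json(bundle, file.path(out_dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  log <- c(sprintf("neqfe run, seed = %d", res$seed),
           sprintf("config md5 = %s", cfg_hash),
           sprintf("R version = %s", R.version.string),
           sprintf("timestamp = %s", format(Sys.time(), usetz = TRUE)))
  writeLines(log, file.path(out_dir, "run.log"))
  message(paste(log[1:2], collapse = "; "))
  invisible(out_dir)
}

#' @export
print.neqfe_run <- function(x, ...) {
  cat("<neqfe_run>", if (is.null(x$estimates)) 0 else
    length(unique(paste(x$estimates$tau_ns, x$estimates$k_rstr))),
    "condition(s), seed =", x$seed, "\n")
  if (!is.null(x$abfe)) {
    cat("ABFE (binding convention, kcal/mol):\n")
    print(x$abfe, row.names = FALSE)
  }
  invisible(x)
}

#' Internal-consistency checks of an analysis run
#'
#' Verifies, on the full-precision tables of a [run_analysis()] result:
#' the ABFE arithmetic (`abfe = raw + corr_total` per row), the restraint
#' correction K-scaling across conditions
#' (`dAr(K2) - dAr(K1) = 3 RT ln(K2/K1)`), and the dissipation identity of
#' every fitted condition (`W_d = <W> -/+ dG_BAR`).
#'
#' @param run a `neqfe_run` object.
#' @param tol numeric tolerance in kcal/mol.
#' @return a data.frame with columns `check`, `where`, `pass`, `detail`;
#'   each failed row pinpoints the offending cell.
#' @export
report_consistency <- function(run, tol = 1e-8) {
  stopifnot(inherits(run, "neqfe_run"))
  rows <- list()
  add <- function(check, where, pass, detail = "")
    rows[[length(rows) + 1L]] <<- data.frame(check = check, where = where,
                                             pass = pass, detail = detail)
  if (!is.null(run$abfe))
    for (i in seq_len(nrow(run$abfe))) {
      r <- run$abfe[i, ]
      dev <- abs(r$abfe - (r$raw + r$corr_total))
      add("abfe_arithmetic",
          sprintf("tau=%g,K=%g", r$tau_ns, r$k_rstr), dev <= tol,
          sprintf("|abfe - (raw + corr)| = %.3g", dev))
    }
  co <- run$corrections
  if (!is.null(co) && any(is.finite(co$dAr))) {
    co <- co[is.finite(co$dAr), ]
    ks <- sort(unique(co$k_rstr))
    if (length(ks) >= 2L) {
      temperature_K <- if (!is.null(run$fits) && length(run$fits))
        run$fits[[1L]]$temperature_K else 298.15
      rt <- rt_kcal(temperature_K)
      for (i in seq_len(length(ks) - 1L)) {
        d1 <- mean(co$dAr[co$k_rstr == ks[i + 1L]])
        d0 <- mean(co$dAr[co$k_rstr == ks[i]])
        expect <- 3 * rt * log(ks[i + 1L] / ks[i])
        dev <- abs((d1 - d0) - expect)
        add("dAr_K_scaling", sprintf("K=%g vs K=%g", ks[i + 1L], ks[i]),
            dev <= max(tol, 1e-9), sprintf("deviation = %.3g", dev))
      }
    }
  }
  for (key in names(run$fits)) {
    fit <- run$fits[[key]]
    for (dn in names(fit$diagnostics)) {
      d <- fit$diagnostics[[dn]]
      if (is.null(d$dissipation)) next
      expected <- if (dn == "forward") d$mean_work - d$dissipation$dG_ref
                  else d$mean_work + d$dissipation$dG_ref
      dev <- abs(d$dissipation$w_diss - expected)
      add("dissipation_identity", paste(key, dn), dev <= tol,
          sprintf("deviation = %.3g", dev))
    }
  }
  do.call(rbind, c(rows, list(NULL)))
}
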