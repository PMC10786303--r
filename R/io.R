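# ---- site-by-month CSV ---------------------------------------------------

#' Read a site-by-month CSV into an sts
#'
#' Strict reader for the package's wide layout: first column holds site ids,
#' remaining column headers are ISO year-months (`"YYYY-MM"`) forming one
#' gapless monthly index. Errors carry row/column coordinates; no silent
#' coercion or reordering (reordering to a configured site order is logged
#' via `message()`).
#'
#' @param path CSV file path.
#' @param expected_sites Optional character vector; the result is reordered
#'   to this order and any mismatch in the site set is an error.
#' @param units Units string attached to the result.
#' @return An [sts()].
#' @export
read_site_matrix <- function(path, expected_sites = NULL, units = "") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("need a site column plus at least 2 month columns")
  months <- names(df)[-1]
  nums <- month_num(months)          # errors on malformed headers
  if (is.unsorted(nums, strictly = TRUE)) {
    stop("month columns are not strictly increasing")
  }
  if (any(diff(nums) != 1L)) {
    miss <- num_month(setdiff(seq(nums[1], nums[length(nums)]), nums)[1])
    stop("missing month column: ", miss)
  }
  sites <- as.character(df[[1]])
  if (anyDuplicated(sites)) {
    stop("duplicate site id: ", sites[duplicated(sites)][1])
  }
  v <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(v)) {
    suppressWarnings(vn <- matrix(as.numeric(v), nrow(v), ncol(v)))
    bad <- which(is.na(vn) & !(v %in% c("NA", "")) & !is.na(v),
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("non-numeric cell at row %d (site '%s'), column %s",
                   bad[1, 1], sites[bad[1, 1]], months[bad[1, 2]]))
    }
    v <- vn
  }
  rownames(v) <- sites
  if (!is.null(expected_sites)) {
    if (!setequal(sites, expected_sites)) {
      stop("site set differs from the configured sites; found: ",
           paste(sites, collapse = ", "))
    }
    if (!identical(sites, as.character(expected_sites))) {
      message("reordering sites to the configured order")
      v <- v[as.character(expected_sites), , drop = FALSE]
      sites <- as.character(expected_sites)
    }
  }
  sts(v, site_ids = sites, t0 = months[1], units = units)
}

#' Write an sts to the wide site-by-month CSV layout
#'
#' @param x An [sts()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_matrix <- function(x, path) {
  stopifnot(inherits(x, "sts"))
  df <- data.frame(site = x$site_ids, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert a long table to the wide sts layout
#'
#' Convenience converter from long format (`site`, `month`, `value`, one row
#' per observation) for data stored that way.
#'
#' @param df Long-format data frame.
#' @param units Units string.
#' @return An [sts()].
#' @export
long_format_to_sts <- function(df, units = "") {
  long_to_sts(df, function(z) {
    if (length(z) != 1L) stop("duplicate (site, month) rows in long table")
    z
  }, units)
}

# ---- scenario / config files --------------------------------------------

# numbers are serialized at full precision (17 significant digits), doubles
# kept distinguishable from integers, and vector names preserved, so configs
# round-trip exactly
yaml_precise <- function(x, path) {
  fmt_one <- function(v) {
    if (is.integer(v)) {
      r <- sprintf("%d", v)
    } else {
      r <- sprintf("%.17g", v)
      if (!grepl("[.eE]", r)) r <- paste0(r, ".0")
    }
    class(r) <- "verbatim"
    r
  }
  prep <- function(v) {
    if (is.numeric(v) && length(v) == 1L && is.null(names(v))) {
      fmt_one(v)
    } else if (is.numeric(v)) {
      out <- lapply(seq_along(v), function(i) fmt_one(v[i]))
      names(out) <- names(v)
      out
    } else v
  }
  writeLines(yaml::as.yaml(lapply(x, prep)), path)
}

#' Write / read a cascade scenario as YAML
#'
#' All scenario parameters round-trip exactly (numbers are serialized at
#' full precision).
#'
#' @param s A [cascade_scenario()].
#' @param path YAML file path.
#' @return For the writer, `path` invisibly; for the reader, the scenario.
#' @export
write_scenario <- function(s, path) {
  stopifnot(inherits(s, "cascade_scenario"))
  yaml_precise(unclass(s), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("seasonal_amp", "rho", "ar_coef", "seasonal_phase")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(cascade_scenario, raw)
}

#' Read a cascade run configuration file
#'
#' YAML with two blocks: `files` (variable name to CSV path map; paths are
#' resolved relative to the config file) and `params` (any [run_config()]
#' argument; bands given as `name: [lo, hi]` pairs, which must be
#' non-overlapping and ordered).
#'
#' @param path YAML config path.
#' @return List with `files` (validated path map), `config` ([run_config()]),
#'   and `sites` (optional configured site order).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$files)) stop("config needs a 'files' block")
  base <- dirname(normalizePath(path))
  files <- lapply(raw$files, function(f) {
    p <- if (file.exists(f)) f else file.path(base, f)
    if (!file.exists(p)) stop("input file not found: ", f)
    p
  })
  params <- if (is.null(raw$params)) list() else raw$params
  if (!is.null(params$bands)) {
    b <- lapply(params$bands, function(z) timescale_band(z[[1]], z[[2]]))
    lims <- t(vapply(b, function(z) c(z$lo, z$hi), c(0, 0)))
    if (is.unsorted(lims[, 1]) ||
        any(lims[-1, 1] < lims[-nrow(lims), 2] - 1e-9)) {
      stop("bands must be ordered and non-overlapping")
    }
    params$bands <- b
  }
  sites <- raw$sites
  params <- params[names(params) %in% names(formals(run_config))]
  list(files = files, config = do.call(run_config, params), sites = sites)
}

#' Run the cascade analysis from a configuration file
#'
#' Reads every input CSV named in the config, then calls [run_cascade()].
#'
#' @param path YAML config path (see [read_run_config()]).
#' @return A `"cascade_report"`.
#' @export
run_cascade_files <- function(path) {
  rc <- read_run_config(path)
  data <- lapply(rc$files, read_site_matrix, expected_sites = rc$sites)
  run_cascade(data, rc$config)
}

# ---- report serialization ------------------------------------------------

matrix_csv <- function(m, grid, months, path) {
  df <- data.frame(month = months, m, check.names = FALSE)
  names(df)[-1] <- signif(grid$timescales, 8)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# scalar/tabular portion of the report (what goes into JSON)
report_to_list <- function(report) {
  mf_sum <- function(mf) {
    list(n_sites = mf$n_sites, alpha = mf$alpha, n_rand = mf$n_rand,
         threshold = mf$threshold,
         sig_fraction = sum(mf$sig_mask) / sum(mf$valid_mask))
  }
  strip_fit <- function(m) {
    if (is.null(m)) return(NULL)
    m$fit <- NULL
    m$contributions <- if (length(m$contributions)) m$contributions else NULL
    m$crossterms <- if (length(m$crossterms)) m$crossterms else NULL
    m
  }
  list(schema_version = report$schema_version,
       config = report$config,
       months = list(first = report$months[1],
                     last = report$months[length(report$months)],
                     n = length(report$months)),
       wrack = list(
         meanfield = mf_sum(report$wrack_meanfield),
         screening = list(
           alpha_screen = report$wrack_screening$alpha_screen,
           n_tests = report$wrack_screening$n_tests,
           n_reject_sig = report$wrack_screening$n_reject_sig,
           table = lapply(seq_len(nrow(report$wrack_screening$table)),
                          function(i) as.list(report$wrack_screening$table[i, ]))),
         models = lapply(report$wrack_models, strip_fit)),
       birds = list(
         meanfield = mf_sum(report$bird_meanfield),
         coherence = report$bird_coherence,
         models = lapply(report$bird_models, strip_fit)),
       significance_summary = report$significance_summary)
}

#' Write a cascade report to disk
#'
#' Serializes the scalar results to `report.json` (stable key order, full
#' numeric precision, `null` for empty model bands), exports the mean-field
#' matrices (`|wmf|^2`, phasor mean field, significance mask) and the
#' screening table as CSVs, and writes a `manifest.csv` of files with MD5
#' content hashes. Two runs with the same seed produce byte-identical
#' outputs. Re-reading the JSON ([read_report()]) reconstructs all scalar
#' results exactly.
#'
#' @param report A `"cascade_report"` from [run_cascade()].
#' @param outdir Output directory (created if needed).
#' @return Data frame manifest (file, md5), invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "cascade_report"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create directory ", outdir)
  }
  files <- character()
  jp <- file.path(outdir, "report.json")
  # I(17) = 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(report_to_list(report), jp, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null",
                       pretty = TRUE)
  files <- c(files, jp)
  for (role in c("wrack", "bird")) {
    mf <- report[[paste0(role, "_meanfield")]]
    files <- c(files,
      matrix_csv(abs(mf$wmf)^2, mf$grid, mf$months,
                 file.path(outdir, paste0(role, "_wmf2.csv"))),
      matrix_csv(mf$wpmf_magnitude, mf$grid, mf$months,
                 file.path(outdir, paste0(role, "_wpmf.csv"))),
      matrix_csv(mf$sig_mask * 1, mf$grid, mf$months,
                 file.path(outdir, paste0(role, "_sigmask.csv"))))
  }
  sp <- file.path(outdir, "screening.csv")
  utils::write.csv(report$wrack_screening$table, sp, row.names = FALSE)
  files <- c(files, sp)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_report
#' @param path Path to a `report.json` written by [write_report()].
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
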