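#' Read a beat series from two-column text
#'
#' Canonical format: one beat per line, RR interval (s) followed by the
#' pulse pressure (mmHg) of the beat terminating it; whitespace- or
#' comma-delimited; lines starting with `#` (and inline `#` comments) are
#' ignored.  Prepreceding intervals are derived by lagging the RR column
#' (the first beat's is `NA`).
#'
#' @param path Path to the text file.
#' @return A beat-series tibble with columns `beat`, `t_dia`, `t_dia_prev`,
#'   `pp`.
#' @examples
#' path <- system.file("extdata", "synthetic_af_beats.txt",
#'                     package = "lvstiff")
#' head(read_beat_series(path))
#' @export
read_beat_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  stripped <- sub("#.*$", "", raw)
  keep <- which(trimws(stripped) != "")
  if (!length(keep)) stop("no data lines in ", path)
  parts <- strsplit(trimws(stripped[keep]), "[,[:space:]]+")
  vals <- lapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(v) != 2 || any(is.na(v))) {
      stop("malformed line ", keep[i], " in ", path, ": '",
           trimws(raw[keep[i]]), "' (expected: <RRI s> <PP mmHg>)")
    }
    if (v[1] <= 0) {
      stop("nonpositive RR interval on line ", keep[i], " in ", path)
    }
    if (!is.finite(v[2])) {
      stop("non-finite pulse pressure on line ", keep[i], " in ", path)
    }
    v
  })
  m <- do.call(rbind, vals)
  tibble::tibble(beat = seq_len(nrow(m)), t_dia = m[, 1],
                 t_dia_prev = dplyr::lag(m[, 1]), pp = m[, 2])
}

#' Write a beat series as two-column text
#'
#' Inverse of [read_beat_series()] (lossless to the printed precision).
#'
#' @param data A beat-series tibble.
#' @param path Output path.
#' @param digits Significant digits (default 10).
#' @return `path`, invisibly.
#' @export
write_beat_series <- function(data, path, digits = 10) {
  lines <- c("# RR interval (s)  pulse pressure (mmHg)",
             sprintf("%.*g %.*g", digits, data$t_dia, digits, data$pp))
  writeLines(lines, path)
  invisible(path)
}

# internal: check/complete a beat-series data frame
validate_beat_series <- function(data, model = "simple") {
  data <- tibble::as_tibble(data)
  if (!all(c("t_dia", "pp") %in% names(data))) {
    stop("a beat series needs columns t_dia and pp")
  }
  if (!"t_dia_prev" %in% names(data)) {
    data$t_dia_prev <- dplyr::lag(data$t_dia)
  }
  if (any(is.na(data$t_dia)) || any(data$t_dia <= 0)) {
    stop("all filling intervals must be positive")
  }
  if (any(!is.finite(data$pp))) stop("all pulse pressures must be finite")
  if (model == "expanded" && sum(!is.na(data$t_dia_prev)) < 2) {
    stop("the expanded model needs at least 2 beats with a prepreceding ",
         "interval")
  }
  data
}

#' Summary table of fitted datasets
#'
#' One row per dataset in the style of a per-patient results table: beat
#' statistics, fraction of variation explained, and the headline parameter
#' estimates with their error estimates for whichever of the two models were
#' fitted.  All values are rounded to three significant figures.
#'
#' @param fits A named list; each element is either a single `lvstiff_fit`
#'   or a list of fits of the same dataset (e.g. `list(sm, em)`).
#' @return A tibble with columns `dataset`, `n_beats`, `mean_rr`, `sd_rr`,
#'   `mean_pp`, `sd_pp`, then per fitted model `fve_*`, `beta_*`,
#'   `beta_ee_*`, `alpha_*`, `alpha_ee_*` (`*` = `simple`/`expanded`),
#'   `flags`, `seed`.
#' @export
result_table <- function(fits) {
  if (inherits(fits, "lvstiff_fit")) fits <- list(fits)
  if (is.null(names(fits))) {
    names(fits) <- paste0("dataset", seq_along(fits))
  }
  purrr::imap_dfr(fits, function(fl, label) {
    if (inherits(fl, "lvstiff_fit")) fl <- list(fl)
    data <- fl[[1]]$data
    s3 <- function(x) signif(x, 3)
    row <- tibble::tibble(
      dataset = label, n_beats = nrow(data),
      mean_rr = s3(mean(data$t_dia)), sd_rr = s3(stats::sd(data$t_dia)),
      mean_pp = s3(mean(data$pp)), sd_pp = s3(stats::sd(data$pp))
    )
    flags <- character(0)
    seeds <- integer(0)
    for (f in fl) {
      m <- f$model
      ee <- function(term) {
        if (is.null(f$errors)) NA_real_ else s3(f$errors[[term]])
      }
      row[[paste0("fve_", m)]] <- s3(f$fve)
      row[[paste0("beta_", m)]] <- s3(f$params[["beta"]])
      row[[paste0("beta_ee_", m)]] <- ee("beta")
      row[[paste0("alpha_", m)]] <- s3(f$params[["alpha"]])
      row[[paste0("alpha_ee_", m)]] <- ee("alpha")
      if (length(f$flags)) flags <- union(flags, paste0(m, ":", f$flags))
      seeds <- union(seeds, f$seed)
    }
    row$flags <- paste(flags, collapse = ";")
    row$seed <- paste(seeds, collapse = ";")
    row
  })
}

#' Write a results table to CSV
#'
#' @param table A tibble from [result_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Serializes a run configuration (model kind, noise SD, sampler settings,
#' diagnostic thresholds, generator settings, seed, paths) to YAML and back.
#' The round trip is the identity for any list of scalars, vectors and
#' nested lists.
#'
#' @param config A named list.
#' @param path File path.
#' @return `read_run_config()` returns the list; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for configuration files")
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for configuration files")
  }
  yaml::read_yaml(path)
}
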