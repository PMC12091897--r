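#' Write / read a trace as CSV
#'
#' The CSV has the header `time_ms,Vs,Vd,h,n,s,c,q,Ca` and full
#' double-precision values (17 significant digits), so a written trace reads
#' back bit-identically; regime boundaries can hinge on small differences.
#'
#' @param trace a `pr_trace`.
#' @param path file path.
#' @return `pr_write_trace` returns `path` invisibly; `pr_read_trace`
#'   returns a `pr_trace` (integration metadata attributes are
#'   reconstructed from the time column where possible).
#' @export
pr_write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  df <- as.data.frame(trace)
  names(df)[names(df) == "time"] <- "time_ms"
  cols <- c("time_ms", "Vs", "Vd", "h", "n", "s", "c", "q", "Ca")
  df <- df[, cols]
  txt <- vapply(seq_len(nrow(df)), function(i)
    paste(sprintf("%.17g", as.numeric(df[i, ])), collapse = ","),
    character(1))
  writeLines(c(paste(cols, collapse = ","), txt), path)
  invisible(path)
}

#' @rdname pr_write_trace
#' @export
pr_read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_ms", "Vs", "Vd", "h", "n", "s", "c", "q", "Ca")
  if (!all(need %in% names(df)))
    stop("not a trace CSV: expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  names(df)[names(df) == "time_ms"] <- "time"
  dt <- if (nrow(df) > 1L) stats::median(diff(df$time)) else NA_real_
  structure(df, class = c("pr_trace", "data.frame"), params = NULL,
            Ve = NA_real_, dt = dt, duration = max(df$time),
            record_stride = NA_integer_, diverged = FALSE,
            divergence_time = NA_real_)
}

#' Write a scan as CSV (with JSON provenance sidecar)
#'
#' Long format `axis1,axis2,F_hz,regime`; one-dimensional scans carry `NA`
#' in `axis2`. When `sidecar = TRUE` a `<path>.json` file records the full
#' parameter set, classifier criteria and integration settings alongside
#' the data.
#'
#' @param scan a `pr_scan`.
#' @param path file path for the CSV.
#' @param sidecar write the JSON provenance file.
#' @return `path`, invisibly.
#' @export
pr_write_scan <- function(scan, path, sidecar = TRUE) {
  stopifnot(inherits(scan, "pr_scan"))
  axes <- attr(scan, "axes")
  out <- data.frame(axis1 = scan[[axes[1]]],
                    axis2 = if (length(axes) > 1L) scan[[axes[2]]] else NA,
                    F_hz = scan$F_hz, regime = scan$regime)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(axes = axes,
                 params = unclass(attr(scan, "params")),
                 criteria = unclass(attr(scan, "criteria")),
                 dt = attr(scan, "dt"), duration = attr(scan, "duration"))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write a spike train as CSV
#'
#' Single column `spike_time_ms`.
#'
#' @param spikes a `pr_spikes` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
pr_write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "pr_spikes"))
  writeLines(c("spike_time_ms", sprintf("%.17g", spikes$times)), path)
  invisible(path)
}

.config_keys <- function() {
  c(names(unclass(pr_params())), "Ve", "dt", "duration", "record_stride",
    names(unclass(pr_criteria())))
}

#' Read a flat key = value configuration file
#'
#' The file holds `key = value` lines (`#` starts a comment; blank lines
#' ignored). Recognised keys are the model parameters (`p`, `Cm`, `gc`,
#' `gL`, `gNa`, `gKDR`, `gCa`, `gKAHP`, `gKC`, `VNa`, `VCa`, `VK`, `VL`,
#' `Vsyn`, `Is`, `Id`), the field amplitude `Ve`, the integration settings
#' (`dt`, `duration`, `record_stride`) and the classifier criteria. Unset
#' keys resolve to the package defaults; unknown keys are an error naming
#' the key. An empty (or absent content) file yields the full default
#' configuration.
#'
#' @param path file path.
#' @return A list with components `params` ([pr_params()]), `Ve`, `sim`
#'   (list `dt`, `duration`, `record_stride`) and `criteria`
#'   ([pr_criteria()]).
#' @export
pr_load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- m[2]
    if (!key %in% .config_keys())
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    val <- suppressWarnings(as.numeric(m[3]))
    if (is.na(val))
      stop("value for key '", key, "' is not numeric: '", m[3], "'",
           call. = FALSE)
    kv[[key]] <- val
  }
  par_keys <- intersect(names(kv), names(unclass(pr_params())))
  cri_keys <- intersect(names(kv), names(unclass(pr_criteria())))
  list(params = do.call(pr_params, kv[par_keys]),
       Ve = if (!is.null(kv$Ve)) kv$Ve else 0,
       sim = list(dt = if (!is.null(kv$dt)) kv$dt else 0.1,
                  duration = if (!is.null(kv$duration)) kv$duration else 7000,
                  record_stride =
                    if (!is.null(kv$record_stride)) as.integer(kv$record_stride)
                    else 1L),
       criteria = do.call(pr_criteria, kv[cri_keys]))
}
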