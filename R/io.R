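#' Read and write single-cell event tables
#'
#' The CSV dialect has header `time_min,value_au` and one row per cell
#' per measurement time. FCS 3.0/3.1 files (one per time point) are
#' supported when the optional \pkg{flowCore} package is installed.
#'
#' @param path file path (CSV) or, for FCS, a named vector of paths whose
#'   names are the measurement times in minutes.
#' @param format `"csv"` or `"fcs"`.
#' @param channel FCS channel to extract (required for `format = "fcs"`).
#' @return An [event_table()].
#' @export
read_event_table <- function(path, format = c("csv", "fcs"),
                             channel = NULL) {
  format <- match.arg(format)
  if (format == "fcs") return(read_event_table_fcs(path, channel))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(gsub("[\"' ]", "", header), "time_min,value_au"))
    stop("malformed event-table CSV: expected header 'time_min,value_au', ",
         "got '", header, "'", call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  tm <- suppressWarnings(as.numeric(df$time_min))
  va <- suppressWarnings(as.numeric(df$value_au))
  bad <- which(!is.finite(tm) | !is.finite(va))
  if (length(bad))
    stop(sprintf("malformed event-table row at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  times <- sort(unique(tm))
  event_table(times, lapply(times, function(t) va[tm == t]))
}

read_event_table_fcs <- function(paths, channel) {
  if (!requireNamespace("flowCore", quietly = TRUE))
    stop("reading FCS files requires the optional 'flowCore' package; ",
         "install it or convert the data to the CSV dialect ",
         "(header 'time_min,value_au')", call. = FALSE)
  if (is.null(channel)) stop("an FCS channel name is required",
                             call. = FALSE)
  if (is.null(names(paths)))
    stop("FCS paths must be named by measurement time (minutes)",
         call. = FALSE)
  times <- as.numeric(names(paths))
  ord <- order(times)
  vals <- lapply(paths[ord], function(p) {
    fr <- flowCore::read.FCS(p, transformation = FALSE)
    cols <- flowCore::colnames(fr)
    if (!channel %in% cols)
      stop("unknown FCS channel '", channel, "'; available: ",
           paste(cols, collapse = ", "), call. = FALSE)
    as.numeric(flowCore::exprs(fr)[, channel])
  })
  event_table(times[ord], vals)
}

#' @rdname read_event_table
#' @param x an [event_table()].
#' @export
write_event_table <- function(x, path) {
  df <- data.frame(
    time_min = rep(x$times, x$nm),
    value_au = unlist(x$values, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration for the command-line interface
#'
#' Reads a YAML configuration carrying the precondition band, the
#' stochastic repetition count, binning policy, optimizer settings and
#' optional bounds overrides; missing fields take the documented
#' defaults (`beta_low = 0.95`, `beta_up = 1.05`, `ns = 1000`,
#' `penalty = 1e12`, `phi = 1`).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A validated named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(beta_low = 0.95, beta_up = 1.05, ns = 1000L,
                   penalty = 1e12, phi = 1, L = NULL,
                   optimizer = list(), bounds = list())
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, cfg)
  stopifnot(out$ns >= 1, out$penalty > 0, out$phi > 0)
  if (any(out$beta_low < 0) || any(out$beta_low > 1) ||
      any(out$beta_up < 1))
    stop("config requires 0 <= beta_low <= 1 <= beta_up", call. = FALSE)
  out
}

# build fit_config from a run config list
config_from_run <- function(rc) {
  fit_config(ns = rc$ns,
             precondition = precondition_config(beta_low = rc$beta_low,
                                                beta_up = rc$beta_up,
                                                penalty = rc$penalty),
             L = rc$L)
}

# apply bounds overrides from a run config to a parameter space
space_with_overrides <- function(space, bounds) {
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (!nm %in% names(space$lower))
      stop("bounds override for unknown parameter: ", nm, call. = FALSE)
    space$lower[nm] <- b[[1]]
    space$upper[nm] <- b[[2]]
  }
  if (any(space$lower <= 0) || any(space$upper <= space$lower))
    stop("overridden bounds must satisfy 0 < lower < upper",
         call. = FALSE)
  space
}

#' Export a fit result as JSON
#'
#' Versioned JSON document with the best parameters, objective value,
#' the full evaluation trace (including precondition decisions and
#' per-evaluation seeds) and the configuration snapshot, so that any
#' recorded evaluation can be replayed exactly.
#'
#' @param fit a `stochfit` object.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  doc <- list(
    schema = "stochfit/fit-result/1",
    method = fit$method,
    model = fit$network$description,
    seed = fit$seed,
    modes = fit$modes,
    config = list(ns = fit$config$ns,
                  beta_low = fit$config$precondition$beta_low,
                  beta_up = fit$config$precondition$beta_up,
                  penalty = fit$config$precondition$penalty,
                  L = fit$config$L),
    best = list(params = as.list(fit$best_params),
                value = fit$best_value,
                eval = fit$best_index,
                eval_seed = fit$trace$eval_seed[fit$best_index]),
    pass_rate = fit$pass_rate,
    generation_best = fit$generation_best,
    trace = fit$trace)
  jsonlite::write_json(doc, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
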