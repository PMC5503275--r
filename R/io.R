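# File round-tripping for traces, configs and scenario files.

#' Write and read index traces
#'
#' Trace CSVs have columns `time_s,<name>,valid`; spectral trace CSVs have
#' `time_s,vlf,lf,hf,nhf,total`. Values are written with 12 significant
#' digits so the round trip is lossless to well below 1e-9.
#'
#' @param trace An [index_trace()] or [spectral_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "index_trace")) {
    df <- data.frame(time_s = sprintf("%.12g", trace$times),
                     value = sprintf("%.12g", trace$values),
                     valid = tolower(trace$valid))
    names(df)[2L] <- trace$name
  } else if (inherits(trace, "spectral_trace")) {
    df <- as.data.frame(lapply(trace, function(col) sprintf("%.12g", col)))
  } else stop("not a trace object")
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                   na.strings = c("NA", "nan"))
  if ("valid" %in% names(df)) {
    name <- setdiff(names(df), c("time_s", "valid"))[1L]
    index_trace(df$time_s, df[[name]], name = name)
  } else {
    structure(df, class = c("spectral_trace", "data.frame"))
  }
}

#' Read a scenario file
#'
#' Scenario files are flat YAML maps whose keys mirror the
#' [scenario_config()] arguments. The `yaml` package is used when
#' installed; otherwise a built-in reader for flat `key: value` maps
#' (comments and blank lines allowed) is applied.
#'
#' @param path Path to the scenario file.
#' @return A validated [scenario_config()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  vals <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    .read_flat_yaml(path)
  }
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  do.call(scenario_config, vals)
}

# minimal flat "key: value" reader (fallback when yaml is unavailable)
.read_flat_yaml <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse scenario line: ", ln)
    val <- m[3L]
    num <- suppressWarnings(as.numeric(val))
    out[[m[2L]]] <- if (!is.na(num)) num else gsub("^['\"]|['\"]$", "", val)
  }
  out
}

#' Serialize the resolved configuration next to outputs
#'
#' Every output directory the CLI writes receives the fully-resolved
#' configuration and the package version, for provenance.
#'
#' @param config A list (e.g. a [scenario_config()] or run configuration).
#' @param dir Output directory.
#' @return The path of the written JSON, invisibly.
#' @export
write_config <- function(config, dir) {
  payload <- c(unclass(config),
               list(fsindex_version = as.character(utils::packageVersion("fsindex"))))
  path <- file.path(dir, "config.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
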