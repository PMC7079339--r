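# Configuration and deterministic output formats. One tabular dialect
# is used everywhere: comma-separated text with a header row and '.'
# decimal separator. Structured metadata (the fully resolved
# configuration, seed, package version) goes into a JSON sidecar next to
# each table so outputs are self-describing and re-runnable.

.known_ops <- c("equilibria", "bifurcation", "simulate", "grid", "figure")

.param_names <- function(model) {
  switch(model,
    base = names(formals(base_params)),
    saturation = names(formals(saturation_params)),
    nkctl = names(formals(nkctl_params)),
    stop("unknown model: ", model, call. = FALSE))
}

#' Load and validate a run configuration
#'
#' Reads a flat configuration file -- JSON, or a plain `key: value`
#' dialect (one pair per line, `#` comments allowed) -- resolves presets
#' and defaults, and validates the result. Required key: `model`
#' (`base`, `saturation` or `nkctl`). Optional: `preset` (see
#' [param_preset()]), `operation` (one of `equilibria`, `bifurcation`,
#' `simulate`, `grid`, `figure`), `seed`, `out`, and model parameter
#' overrides by name. Unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return A list of class `run_config` with `model`, `operation`,
#'   `params` (a validated `cisi_params`), `seed`, `out`, and the raw
#'   key-value map in `$raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  raw <- if (any(grepl("^\\s*\\{", txt))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
  } else {
    lines <- trimws(sub("#.*$", "", txt))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) list() else {
      kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$",
                                      lines))
      bad <- lines[vapply(kv, length, integer(1)) != 3]
      if (length(bad)) stop("unparseable config line(s): ",
                            paste(bad, collapse = "; "), call. = FALSE)
      vals <- lapply(kv, function(m) {
        v <- trimws(m[3])
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num)) num else v
      })
      stats::setNames(vals, vapply(kv, `[`, character(1), 2))
    }
  }
  if (!length(raw) || is.null(raw$model)) {
    stop("config must specify at least: model (base|saturation|nkctl); ",
         "optional keys: preset, operation, seed, out, and parameter ",
         "overrides", call. = FALSE)
  }
  model <- as.character(raw$model)
  par_names <- .param_names(model)
  meta_keys <- c("model", "preset", "operation", "seed", "out")
  unknown <- setdiff(names(raw), c(meta_keys, par_names))
  if (length(unknown)) {
    stop("unknown config key(s) for model '", model, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- if (!is.null(raw$preset)) {
    preset <- as.character(raw$preset)
    ok <- switch(model, base = c("table1", "fig2"),
                 saturation = "saturation", nkctl = "nkctl")
    if (!preset %in% ok) {
      stop("preset '", preset, "' not valid for model '", model, "'",
           call. = FALSE)
    }
    param_preset(preset)
  } else {
    switch(model, base = base_params(), saturation = saturation_params(),
           nkctl = nkctl_params())
  }
  overrides <- raw[intersect(names(raw), par_names)]
  if (length(overrides)) {
    params <- do.call(update_params, c(list(params), overrides))
  }
  operation <- if (is.null(raw$operation)) NA_character_ else
    match.arg(as.character(raw$operation), .known_ops)
  structure(list(model = model, operation = operation, params = params,
                 seed = if (is.null(raw$seed)) NA_integer_ else
                   as.integer(raw$seed),
                 out = if (is.null(raw$out)) NA_character_ else
                   as.character(raw$out),
                 raw = raw),
            class = "run_config")
}

#' Parameters from a configuration list
#'
#' Programmatic variant of [load_config()]: builds a validated parameter
#' object from an in-memory list with the same keys.
#'
#' @param config Named list with `model`, optional `preset`, and
#'   parameter overrides.
#' @return A `cisi_params` object.
#' @export
params_from_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  load_config(tmp)$params
}

#' Write a result table with a JSON metadata sidecar
#'
#' @param df Data frame to write (comma-separated, header row).
#' @param path Output path; metadata goes to `<path>.meta.json`.
#' @param meta Named list of provenance metadata (resolved config, seed,
#'   ...); the package version is added automatically.
#' @return `path`, invisibly.
#' @export
write_run_table <- function(df, path, meta = list()) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta$package <- paste0("cisim ",
                         as.character(utils::packageVersion("cisim")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a result table and its metadata
#'
#' @param path Path previously written by [write_run_table()].
#' @return The data frame, with the sidecar metadata (if present)
#'   attached as attribute `"meta"`.
#' @export
read_run_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp)) attr(df, "meta") <- jsonlite::fromJSON(mp)
  df
}
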