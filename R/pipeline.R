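#' Pipeline configuration
#'
#' Knobs of the descriptor pipeline. `estrada_shift` selects the exponent shift
#' of the Laplacian-type Estrada indices (`"sigma"` = total transmission, the
#' printed convention; `"t"` = mean transmission, matching the energy
#' centering; `"none"`). `precision` controls decimals in written reports;
#' `exponent_cap` the overflow fallback of [estrada()]; `transpose_nanotube`
#' swaps the (m, n) roles of the nanotube generators.
#'
#' @param estrada_shift `"sigma"`, `"t"` or `"none"`.
#' @param precision Integer 1..12, report decimals.
#' @param exponent_cap Positive real, at most 709.
#' @param transpose_nanotube Logical.
#' @return A list of class `run_config`.
#' @export
run_config <- function(estrada_shift = c("sigma", "t", "none"),
                       precision = 4L,
                       exponent_cap = 700,
                       transpose_nanotube = FALSE) {
  estrada_shift <- match.arg(estrada_shift)
  precision <- as.integer(precision)
  if (is.na(precision) || precision < 1L || precision > 12L)
    stop("`precision` must be in 1..12")
  if (!is.numeric(exponent_cap) || exponent_cap <= 0 || exponent_cap > 709)
    stop("`exponent_cap` must be in (0, 709]")
  structure(list(estrada_shift = estrada_shift,
                 precision = precision,
                 exponent_cap = exponent_cap,
                 transpose_nanotube = isTRUE(transpose_nanotube)),
            class = "run_config")
}

#' Load a pipeline configuration from flat JSON
#'
#' Keys mirror [run_config()] arguments; missing keys take the defaults.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[intersect(names(raw),
    c("estrada_shift", "precision", "exponent_cap", "transpose_nanotube"))])
}

#' Resolve one molecule input specification
#'
#' Input specs are strings: `benzenoid:NAME`, `zigzag:M,N`, `armchair:M,N`,
#' `nanocone:N`, `edgelist:PATH`, `adjacency:PATH`. A bare existing file path
#' is treated as `edgelist:PATH`.
#'
#' @param spec Character scalar.
#' @param config A `run_config`.
#' @return List with `id` (molecule identifier) and `graph`.
#' @export
resolve_input <- function(spec, config = run_config()) {
  stopifnot(is.character(spec), length(spec) == 1L)
  if (file.exists(spec)) spec <- paste0("edgelist:", spec)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  if (length(parts) < 2L)
    stop("cannot parse input spec '", spec, "'")
  kind <- parts[1L]
  arg <- paste(parts[-1L], collapse = ":")
  tp <- config$transpose_nanotube
  switch(kind,
    benzenoid = list(id = arg, graph = benzenoid_catalogue(arg)),
    zigzag = {
      mn <- as.integer(strsplit(arg, ",")[[1L]])
      if (length(mn) != 2L || any(is.na(mn)))
        stop("zigzag spec needs 'zigzag:M,N'")
      list(id = sprintf("ZC6[%d,%d]", mn[1L], mn[2L]),
           graph = make_zigzag_nanotube(mn[1L], mn[2L], transpose = tp))
    },
    armchair = {
      mn <- as.integer(strsplit(arg, ",")[[1L]])
      if (length(mn) != 2L || any(is.na(mn)))
        stop("armchair spec needs 'armchair:M,N'")
      list(id = sprintf("AC6[%d,%d]", mn[1L], mn[2L]),
           graph = make_armchair_nanotube(mn[1L], mn[2L], transpose = tp))
    },
    nanocone = {
      k <- as.integer(arg)
      if (is.na(k)) stop("nanocone spec needs 'nanocone:N'")
      list(id = sprintf("CNC6[%d]", k), graph = make_nanocone(k))
    },
    edgelist = list(id = basename(arg), graph = read_edgelist_tsv(arg)),
    adjacency = list(id = basename(arg), graph = read_adjacency_csv(arg)),
    stop("unknown input kind '", kind, "' in spec '", spec, "'")
  )
}

#' Run the descriptor pipeline
#'
#' Resolves every input (generator spec or file), computes the 33-descriptor
#' record per molecule and optionally writes the descriptor table as CSV (with
#' a JSON sidecar recording the configuration, per-stage timings and any
#' log-domain Estrada flags). Per-molecule failures are recorded and the run
#' continues unless `strict = TRUE`.
#'
#' @param inputs Character vector of input specs (see [resolve_input()]).
#' @param config A [run_config()].
#' @param output Optional CSV path; `NULL` returns the table only.
#' @param strict Abort on the first per-molecule error instead of recording it.
#' @param quiet Suppress progress messages.
#' @return The descriptor table (data.frame, one row per successful molecule;
#'   `molecule` column plus 33 descriptor columns at full precision).
#'   Attributes: `errors` (named character vector of failures), `log_estrada`.
#' @export
run_pipeline <- function(inputs, config = run_config(), output = NULL,
                         strict = FALSE, quiet = TRUE) {
  rows <- list()
  errors <- character(0)
  logged <- character(0)
  for (spec in inputs) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      inp <- resolve_input(spec, config)
      rec <- descriptor_suite(inp$graph, molecule = inp$id, config = config)
      lg <- attr(rec, "log_estrada")
      if (length(lg)) logged[inp$id] <- paste(lg, collapse = ",")
      rec
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop("input '", spec, "' failed: ", conditionMessage(res))
      errors[spec] <- conditionMessage(res)
      if (!quiet) message(sprintf("[fail] %-24s %s", spec, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
      if (!quiet)
        message(sprintf("[ok]   %-24s %.2fs", spec,
                        proc.time()[["elapsed"]] - t0))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = 34)),
                    c("molecule", descriptor_names()))
  attr(tab, "errors") <- errors
  attr(tab, "log_estrada") <- logged
  if (!is.null(output)) {
    write_descriptor_csv(tab, output, precision = config$precision)
    jsonlite::write_json(list(
      config = unclass(config),
      n_molecules = nrow(tab),
      errors = as.list(errors),
      log_estrada = as.list(logged)
    ), paste0(output, ".json"), auto_unbox = TRUE, digits = NA)
  }
  tab
}

#' Write a descriptor table as CSV
#'
#' Header `molecule,rho_DIST,En_DIST,Es_DIST,...` (33 descriptor columns in
#' kind order); values printed with a fixed number of decimals. Byte-identical
#' output for identical input.
#'
#' @param tab Descriptor table from [run_pipeline()] or rbound
#'   [descriptor_suite()] rows.
#' @param path Output CSV path.
#' @param precision Decimals (default 4, the reporting convention of the
#'   reference tables).
#' @export
write_descriptor_csv <- function(tab, path, precision = 4L) {
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(v) formatC(v, format = "f",
                                                   digits = precision))
  utils::write.csv(out, path, row.names = FALSE, quote = 1)
  invisible(path)
}

#' Read back a descriptor CSV
#'
#' @param path CSV path written by [write_descriptor_csv()].
#' @return data.frame.
#' @export
read_descriptor_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
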