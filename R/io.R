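#' Read and write gridded monthly fields
#'
#' Gridded fields are stored in a self-describing plain-text format: a CSV
#' body (`year,month,lat,lon,value`, one row per cell-month, empty `value`
#' for missing) preceded by commented metadata lines carrying the variable
#' name and units, mirroring CF attribute semantics. Values round-trip
#' bitwise. On read, longitudes on a \[0, 360) convention are remapped into
#' \[-180, 180) and rows reordered consistently; latitudes are returned
#' ascending.
#'
#' @param path File path.
#' @param variable Variable name expected in the file. Reading a file whose
#'   recorded variable differs is a format error.
#' @return `read_gridded()` returns a [flux_grid()]; `write_gridded()`
#'   returns `path` invisibly.
#' @export
read_gridded <- function(path, variable) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- parse_header(hdr)
  if (is.null(meta$variable)) {
    abort(sprintf("%s: not a gridded-field file (no '# variable:' header)", path))
  }
  if (!identical(meta$variable, variable)) {
    abort(sprintf(
      "%s: variable '%s' not present (file contains '%s')",
      path, variable, meta$variable
    ))
  }
  body <- readr::read_csv(
    path,
    comment = "#",
    col_types = readr::cols(
      year = readr::col_integer(), month = readr::col_integer(),
      lat = readr::col_double(), lon = readr::col_double(),
      value = readr::col_character()
    ),
    progress = FALSE
  )
  # strtod is correctly rounded, guaranteeing the bitwise round-trip
  body$value <- as.numeric(body$value)
  body$lon <- normalize_lon(body$lon)
  flux_grid(body, variable = meta$variable, units = meta$units %||% "")
}

#' @rdname read_gridded
#' @param grid A [flux_grid()] satisfying its invariants.
#' @export
write_gridded <- function(grid, path) {
  stopifnot(inherits(grid, "flux_grid"))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(c(
    sprintf("# variable: %s", fg_variable(grid)),
    sprintf("# units: %s", fg_units(grid)),
    "# missing_value: empty field"
  ), con)
  out <- as_tibble(grid)
  # %.17g guarantees bitwise round-trip of doubles through the text format
  out$value <- ifelse(is.na(out$value), NA_character_,
                      sprintf("%.17g", out$value))
  readr::write_csv(out, con, na = "")
  invisible(path)
}

parse_header <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

# map degrees east into [-180, 180)
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}
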