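# Standardized nomenclature and unit enforcement for gas-exchange tables.
#
# Every analysis in the package consumes a "standard table": a tidy tibble
# whose columns use one canonical vocabulary (A_net, Q, C_i, T_leaf, ...) in
# one canonical unit set (temperatures in K, fluxes in umol m-2 s-1, RH as a
# fraction). Instrument exports use other dialects (e.g. the Li-Cor 6400
# reports net assimilation as "Photo", the 6800 as "A"); a varname map
# translates them.

#' Canonical column vocabulary
#'
#' The standardized column names used throughout the package, with their
#' canonical units and physical dimension. Temperatures are always stored in
#' Kelvin, gas fluxes in umol m-2 s-1, conductances in mol m-2 s-1, relative
#' humidity and PSII efficiency as fractions, water potential in MPa.
#'
#' @return A tibble with columns `name`, `unit`, `dimension`, `description`.
#' @export
canonical_vocabulary <- function() {
  tibble::tribble(
    ~name,       ~unit,            ~dimension,     ~description,
    "A_net",     "umol m-2 s-1",   "co2_flux",     "net CO2 assimilation rate",
    "Q",         "umol m-2 s-1",   "co2_flux",     "photosynthetic photon flux density (PPFD)",
    "C_i",       "umol mol-1",     "mole_frac",    "intercellular CO2 mole fraction",
    "C_a",       "umol mol-1",     "mole_frac",    "ambient CO2 mole fraction",
    "C_s",       "umol mol-1",     "mole_frac",    "leaf-surface CO2 mole fraction",
    "g_sw",      "mol m-2 s-1",    "conductance",  "stomatal conductance to water vapour",
    "T_leaf",    "K",              "temperature",  "leaf temperature",
    "T_air",     "K",              "temperature",  "air temperature",
    "RH",        "fraction",       "fraction",     "relative humidity",
    "D",         "kPa",            "pressure_kpa", "vapour pressure deficit",
    "phi_PSII",  "fraction",       "fraction",     "PSII operating efficiency",
    "J_F",       "umol m-2 s-1",   "co2_flux",     "fluorescence-derived electron transport rate",
    "psi",       "MPa",            "pressure_mpa", "water potential",
    "PLC",       "%",              "percent",      "percent loss of hydraulic conductivity",
    "mass",      "g",              "mass",         "leaf fresh mass",
    "RWC",       "%",              "percent",      "relative water content",
    "rate",      "umol m-2 s-1",   "co2_flux",     "generic rate for temperature-response fitting"
  )
}

# Recognized unit strings per dimension; canonical value = value * scale + offset.
.unit_table <- function() {
  tibble::tribble(
    ~unit,            ~dimension,     ~scale, ~offset,
    "K",              "temperature",  1,      0,
    "degC",           "temperature",  1,      273.15,
    "C",              "temperature",  1,      273.15,
    "°C",        "temperature",  1,      273.15,
    "umol m-2 s-1",   "co2_flux",     1,      0,
    "mmol m-2 s-1",   "co2_flux",     1000,   0,
    "mol m-2 s-1",    "co2_flux",     1e6,    0,
    "umol mol-1",     "mole_frac",    1,      0,
    "ppm",            "mole_frac",    1,      0,
    "mmol mol-1",     "mole_frac",    1000,   0,
    "mol m-2 s-1",    "conductance",  1,      0,
    "mmol m-2 s-1",   "conductance",  1e-3,   0,
    "fraction",       "fraction",     1,      0,
    "%",              "fraction",     0.01,   0,
    "kPa",            "pressure_kpa", 1,      0,
    "Pa",             "pressure_kpa", 1e-3,   0,
    "MPa",            "pressure_kpa", 1e3,    0,
    "MPa",            "pressure_mpa", 1,      0,
    "kPa",            "pressure_mpa", 1e-3,   0,
    "bar",            "pressure_mpa", 0.1,    0,
    "%",              "percent",      1,      0,
    "fraction",       "percent",      100,    0,
    "g",              "mass",         1,      0,
    "mg",             "mass",         1e-3,   0,
    "kg",             "mass",         1e3,    0
  )
}

#' Built-in instrument varname maps
#'
#' Column-name translation maps shipped with the package, loaded from
#' editable CSV config files under `inst/extdata/`. The `licor6400` and
#' `licor6800` dialects are transcribed from the respective instrument
#' manuals (e.g. net assimilation is `Photo` on the 6400 and `A` on the
#' 6800); edit the CSVs or supply your own named vector to adapt to local
#' export settings.
#'
#' @param dialect one of `"licor6400"`, `"licor6800"`.
#' @return Named character vector: names are canonical column names, values
#'   are source column names.
#' @examples
#' varnames("licor6800")[["A_net"]]
#' @export
varnames <- function(dialect = c("licor6400", "licor6800")) {
  dialect <- match.arg(dialect)
  path <- system.file("extdata", paste0("varnames_", dialect, ".csv"),
                      package = "photofit", mustWork = TRUE)
  map <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(map$source, map$canonical)
}

#' Translate instrument column names to the canonical vocabulary
#'
#' Renames columns of a raw instrument export to the standardized names used
#' throughout the package. Unmapped columns are carried through untouched and
#' listed in the `"unmapped"` attribute of the result so their provenance
#' stays visible.
#'
#' @param raw_table data frame as exported by the instrument.
#' @param varnames named character vector mapping canonical name -> source
#'   column name (as returned by [varnames()]), or a list coercible to one.
#' @return A tibble with canonical column names; attributes `"varnames"` (the
#'   map applied) and `"unmapped"` (raw columns carried through unrenamed).
#' @examples
#' raw <- data.frame(PHOTO = c(10, 12), PARi = c(500, 1500))
#' standardize_columns(raw, c(A_net = "PHOTO", Q = "PARi"))
#' @export
standardize_columns <- function(raw_table, varnames) {
  stopifnot(is.data.frame(raw_table))
  vn <- unlist(varnames)
  if (is.null(names(vn)) || any(!nzchar(names(vn)))) {
    abort("`varnames` must be a named vector: canonical name -> source column")
  }
  if (anyDuplicated(names(vn))) {
    dup <- unique(names(vn)[duplicated(names(vn))])
    abort(paste0("multiple source columns map to one canonical name: ",
                 paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(vn)) {
    dup <- unique(vn[duplicated(vn)])
    abort(paste0("source column(s) used more than once: ",
                 paste(dup, collapse = ", ")))
  }
  missing <- setdiff(vn, names(raw_table))
  if (length(missing) > 0) {
    abort(paste0("source column(s) absent from raw table: ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw_table)
  idx <- match(vn, names(out))
  names(out)[idx] <- names(vn)
  if (anyDuplicated(names(out))) {
    dup <- unique(names(out)[duplicated(names(out))])
    abort(paste0("duplicate canonical column names after translation: ",
                 paste(dup, collapse = ", ")))
  }
  attr(out, "varnames") <- vn
  attr(out, "unmapped") <- setdiff(names(out), names(vn))
  out
}

#' Convert declared column units to the canonical unit set
#'
#' Converts columns reported in recognized non-canonical units (e.g. degC,
#' mmol m-2 s-1, % relative humidity) to the canonical units of
#' [canonical_vocabulary()], and records the resulting units in the table's
#' `"units"` attribute. Calling it again without new declarations is a no-op,
#' so the conversion is idempotent.
#'
#' @param table a standard table (canonical column names).
#' @param declared_units named character vector column -> unit string for the
#'   units the values are currently in. Columns not mentioned are assumed
#'   canonical (or keep their previously recorded unit).
#' @return The table with converted values and an updated `"units"` attribute.
#' @examples
#' tb <- tibble::tibble(T_leaf = 25, RH = 65)
#' enforce_units(tb, c(T_leaf = "degC", RH = "%"))
#' @export
enforce_units <- function(table, declared_units = NULL) {
  stopifnot(is.data.frame(table))
  vocab <- canonical_vocabulary()
  units_attr <- attr(table, "units")
  if (is.null(units_attr)) units_attr <- character(0)
  du <- unlist(declared_units)
  out <- tibble::as_tibble(table)
  ut <- .unit_table()
  for (col in names(du)) {
    if (!col %in% names(out)) {
      abort(paste0("declared unit for absent column: ", col))
    }
    dim_row <- vocab[vocab$name == col, ]
    if (nrow(dim_row) == 0) next # non-canonical column: no enforced unit
    unit <- du[[col]]
    known <- ut[ut$unit == unit, ]
    if (nrow(known) == 0) {
      abort(paste0("unknown unit string '", unit, "' for column ", col))
    }
    conv <- known[known$dimension == dim_row$dimension, ]
    if (nrow(conv) == 0) {
      abort(paste0("unit '", unit, "' is dimensionally incompatible with ",
                   col, " (expected ", dim_row$dimension, ", canonical unit ",
                   dim_row$unit, ")"))
    }
    out[[col]] <- out[[col]] * conv$scale[1] + conv$offset[1]
    units_attr[col] <- dim_row$unit
  }
  # columns never declared default to canonical units
  for (col in intersect(names(out), vocab$name)) {
    if (!col %in% names(units_attr)) {
      units_attr[col] <- vocab$unit[vocab$name == col]
    }
  }
  attr(out, "units") <- units_attr
  attr(out, "varnames") <- attr(table, "varnames")
  attr(out, "unmapped") <- attr(table, "unmapped")
  validate_standard_table(out)
  out
}

#' Validate a standard table's physical ranges
#'
#' Errors on physically impossible values (negative absolute temperature,
#' relative humidity outside 0-1, PLC outside 0-100, duplicate canonical
#' columns) and warns on suspicious leaf temperatures (outside 263-333 K,
#' i.e. -10 to 60 degC), which usually indicate values still in Celsius.
#'
#' @param table a standard table.
#' @return `table`, invisibly.
#' @export
validate_standard_table <- function(table) {
  if (anyDuplicated(names(table))) {
    abort("duplicate column names in standard table")
  }
  chk <- function(x) x[is.finite(x)]
  if ("T_leaf" %in% names(table)) {
    tl <- chk(table$T_leaf)
    if (any(tl < 0)) abort("T_leaf below 0 K is not a physical temperature")
    if (length(tl) && (any(tl < 263) || any(tl > 333))) {
      warn("T_leaf outside 263-333 K: are temperatures really in Kelvin?")
    }
  }
  if ("RH" %in% names(table)) {
    rh <- chk(table$RH)
    if (any(rh < 0 | rh > 1)) {
      abort("RH outside [0, 1]: declare percent values with enforce_units()")
    }
  }
  if ("PLC" %in% names(table)) {
    plc <- chk(table$PLC)
    if (any(plc < 0 | plc > 100)) abort("PLC outside [0, 100]")
  }
  invisible(table)
}

#' Read a gas-exchange or hydraulics table from CSV/TSV
#'
#' Thin reader around [utils::read.table()] that applies a varname map and
#' declared units on the way in, yielding an analysis-ready standard table.
#'
#' @param path file path.
#' @param delim field delimiter (default `","`; use `"\t"` for TSV).
#' @param varnames optional dialect name (see [varnames()]) or named map.
#' @param declared_units optional named vector of source units (canonical
#'   column name -> unit), passed to [enforce_units()].
#' @param header_row 1-based row number of the header (rows above are skipped).
#' @param decimal_mark decimal separator in the file.
#' @param comment_prefix lines starting with this prefix are ignored.
#' @return A standard table (tibble).
#' @export
read_gas_exchange <- function(path, delim = ",", varnames = NULL,
                              declared_units = NULL, header_row = 1,
                              decimal_mark = ".", comment_prefix = "#") {
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           skip = header_row - 1, dec = decimal_mark,
                           comment.char = comment_prefix,
                           check.names = FALSE, stringsAsFactors = FALSE)
  raw <- tibble::as_tibble(raw)
  if (!is.null(varnames)) {
    if (is.character(varnames) && length(varnames) == 1 && is.null(names(varnames))) {
      varnames <- varnames(varnames)
    }
    # drop map entries whose source is absent (instrument configs vary)
    varnames <- varnames[varnames %in% names(raw)]
    raw <- standardize_columns(raw, varnames)
  }
  enforce_units(raw, declared_units)
}

#' Write a standard table as canonical CSV with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the units of every canonical column
#' and the varname map used to translate the source, so the provenance of a
#' processed file is machine-readable.
#'
#' @param table a standard table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_standard_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  sidecar <- list(
    units = as.list(attr(table, "units") %||% list()),
    varnames = as.list(attr(table, "varnames") %||% list())
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
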