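#' @title Soil property and spiking-experiment tables
#' @description Readers, writers and validators for the two tabular inputs of
#'   the pipeline: intact soil physicochemical properties (`soils.csv`
#'   schema) and solution-phase cation concentrations measured in spiked
#'   soils (`spiked.csv` schema).  Two fixtures ship with the package:
#'   `table1_soils.csv` (17 soils of 4 types) and `table3_cations.csv`
#'   (4 soils x 4 cadmium addition levels).
#' @name soil_data
NULL

.soil_types <- c("sandy", "andosol", "brown_forest", "cohesive")

.soil_required_cols <- c("sample_id", "sand", "silt", "clay", "cec", "area",
                         "whc", "ph", "total_c", "ignition_loss", "soil_type")

.spiked_required_cols <- c("sample_id", "cd_add", "cd_add_solution", "cd_dgt",
                           "ca", "mg", "h")

#' Numeric soil properties used by the statistical analyses
#' @export
soil_properties <- c("sand", "silt", "clay", "cec", "area", "whc", "ph",
                     "total_c", "ignition_loss")

#' Path to a packaged example data file
#'
#' @param name file name under the package's `extdata` directory, e.g.
#'   `"table1_soils.csv"`; with no argument, lists the available files.
#' @export
cadsoil_file <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "cadsoil")))
  }
  path <- system.file("extdata", name, package = "cadsoil")
  if (path == "") stop("no packaged file named '", name, "'", call. = FALSE)
  path
}

.read_csv_checked <- function(path, required, table_name) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA", "–", "-"))
  missing <- setdiff(required, names(d))
  if (nrow(d) == 0 || length(missing) == length(required)) {
    stop(table_name, " schema error: ", path,
         if (nrow(d) == 0) " has no data rows" else "",
         if (length(missing) > 0)
           paste0("; missing column(s): ", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (length(missing) > 0) {
    stop(table_name, " schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d
}

.check_numeric_cols <- function(d, cols, table_name) {
  for (col in cols) {
    raw <- d[[col]]
    if (is.numeric(raw)) next
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad) > 0) {
      stop(table_name, " parse error: non-numeric value '", raw[bad[1]],
           "' in column '", col, "', row ", bad[1], call. = FALSE)
    }
    d[[col]] <- parsed
  }
  d
}

#' Read a soil physicochemical property table
#'
#' Expects the `soils.csv` schema: `sample_id`, `location` (optional),
#' texture fractions `sand`, `silt`, `clay` (%), `cec` (cmol/kg), `area`
#' (specific surface area, m2/g; may be missing), `whc` (%), `ph`,
#' `total_c` (%), `ignition_loss` (%), `soil_type` (one of sandy, andosol,
#' brown_forest, cohesive).  An en-dash or empty cell denotes a missing
#' value.  Row invariants are checked: texture fractions sum to 100 within
#' one unit of measurement rounding, pH in (0, 14), CEC strictly positive,
#' everything else non-negative.
#'
#' @param path CSV file path.
#' @return data frame of class `soil_table`, one row per soil.
#' @seealso [write_soil_table()], [read_spiked_table()]
#' @export
read_soil_table <- function(path) {
  d <- .read_csv_checked(path, .soil_required_cols, "soil table")
  d <- .check_numeric_cols(d, soil_properties, "soil table")
  d$soil_type <- .normalize_soil_type(d$soil_type)
  validate_soil_table(d)
  class(d) <- c("soil_table", "data.frame")
  d
}

.normalize_soil_type <- function(x) {
  key <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  key[key %in% c("sandy_soil", "sand")] <- "sandy"
  key[key %in% c("brown_forest_soil")] <- "brown_forest"
  key[key %in% c("cohesive_soil")] <- "cohesive"
  bad <- setdiff(unique(key), .soil_types)
  if (length(bad) > 0) {
    stop("unknown soil type label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(key, levels = .soil_types)
}

#' Validate soil table row invariants
#' @param d a soil table data frame.
#' @return the table, invisibly; errors describe the offending row.
#' @export
validate_soil_table <- function(d) {
  texture <- d$sand + d$silt + d$clay
  bad <- which(abs(texture - 100) > 1)
  if (length(bad) > 0) {
    # warning, not error: reported fraction triplets can fall short of 100
    # when a coarse (>2 mm) fraction is excluded from the three classes
    warning("texture fractions of sample ",
            paste(d$sample_id[bad], collapse = ", "),
            " sum outside 100 +/- 1", call. = FALSE)
  }
  if (any(d$ph <= 0 | d$ph >= 14)) stop("pH outside (0, 14)", call. = FALSE)
  if (any(d$cec <= 0)) stop("CEC must be strictly positive", call. = FALSE)
  nonneg <- c("sand", "silt", "clay", "whc", "total_c", "ignition_loss", "area")
  for (col in nonneg) {
    if (any(d[[col]] < 0, na.rm = TRUE)) {
      stop("negative value in column '", col, "'", call. = FALSE)
    }
  }
  invisible(d)
}

#' Write a soil table to CSV
#'
#' Inverse of [read_soil_table()]: a written table re-reads to an identical
#' collection (missing cells serialized as empty).
#'
#' @param d soil table.
#' @param path output CSV path.
#' @export
write_soil_table <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a spiking-experiment cation table
#'
#' Expects the `spiked.csv` schema: `sample_id`, `cd_add` (mg Cd per kg dry
#' soil), `cd_add_solution` (the same dose expressed as a solution
#' concentration, mM), `cd_dgt` (DGT-measured Cd; micromolar by default, see
#' `cd_dgt_unit`), and solution concentrations `ca`, `mg`, `h` in mM.
#'
#' @param path CSV file path.
#' @param cd_dgt_unit unit of the `cd_dgt` column, `"uM"` (default) or
#'   `"ug_per_L"`; recorded as an attribute on the returned table.
#' @return data frame of class `spiked_table`.
#' @export
read_spiked_table <- function(path, cd_dgt_unit = c("uM", "ug_per_L")) {
  cd_dgt_unit <- match.arg(cd_dgt_unit)
  d <- .read_csv_checked(path, .spiked_required_cols, "spiked table")
  d <- .check_numeric_cols(d, setdiff(.spiked_required_cols, "sample_id"),
                           "spiked table")
  conc <- c("cd_add", "cd_add_solution", "cd_dgt", "ca", "mg", "h")
  for (col in conc) {
    if (any(d[[col]] < 0, na.rm = TRUE)) {
      stop("negative concentration in column '", col, "'", call. = FALSE)
    }
  }
  attr(d, "cd_dgt_unit") <- cd_dgt_unit
  class(d) <- c("spiked_table", "data.frame")
  d
}

#' Write a spiked table to CSV
#' @param d spiked table.
#' @param path output CSV path.
#' @export
write_spiked_table <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE, na = "")
  invisible(path)
}
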