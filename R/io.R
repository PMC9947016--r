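# CSV schemas shared by the generators and the fitting routines. Readers
# validate column names and basic value constraints so that generated
# datasets round-trip without modification.

.viability_cols <- c("condition_id", "c_dox0", "c_dex0", "time_h",
                     "replicate", "viability")
.degradation_cols <- c("drug", "time_h", "conc_um")
.pk_cols <- c("dose_mg_per_m2", "bsa_m2", "time_h", "conc_mg_l",
              "duration_h")

check_cols <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " file ", path, " lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df[, cols]
}

#' Write / read a viability dataset CSV
#'
#' Columns: `condition_id`, `c_dox0` (uM), `c_dex0` (uM), `time_h`,
#' `replicate`, `viability` (%).
#'
#' @param data A viability data frame (see [generate_viability()]).
#' @param path File path.
#' @return The path (write) or the validated data frame (read).
#' @export
write_viability_csv <- function(data, path) {
  validate_viability_data(data)
  write.csv(data[, .viability_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_viability_csv
#' @export
read_viability_csv <- function(path) {
  df <- check_cols(read.csv(path), .viability_cols, "viability", path)
  validate_viability_data(df)
  df
}

#' Write / read a degradation time-course CSV
#'
#' Columns: `drug`, `time_h`, `conc_um`.
#'
#' @param data A degradation data frame (see [generate_degradation()]).
#' @param path File path.
#' @return The path (write) or the validated data frame (read).
#' @export
write_degradation_csv <- function(data, path) {
  stopifnot(all(.degradation_cols %in% names(data)))
  write.csv(data[, .degradation_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_degradation_csv
#' @export
read_degradation_csv <- function(path) {
  df <- check_cols(read.csv(path), .degradation_cols, "degradation", path)
  if (any(df$conc_um <= 0))
    stop("degradation concentrations must be > 0", call. = FALSE)
  df
}

#' Write / read a clinical PK dataset CSV
#'
#' Columns: `dose_mg_per_m2`, `bsa_m2`, `time_h`, `conc_mg_l`,
#' `duration_h`.
#'
#' @param data A PK data frame (see [generate_dex_pk()]).
#' @param path File path.
#' @return The path (write) or the validated data frame (read).
#' @export
write_pk_csv <- function(data, path) {
  stopifnot(all(.pk_cols %in% names(data)))
  write.csv(data[, .pk_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pk_csv
#' @export
read_pk_csv <- function(path) {
  df <- check_cols(read.csv(path), .pk_cols, "PK", path)
  validate_pk_data(df)
  df
}

#' Write a simulated profile to CSV
#'
#' Long-format export for viability or concentration profiles:
#' columns `series`, `time_h`, `value`, `unit`.
#'
#' @param profile Data frame with `time_h` and one value column
#'   (`viability` or `conc_mg_l`).
#' @param path File path.
#' @param series Label for the profile (e.g. drug or condition).
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, series = "profile") {
  vcol <- intersect(c("viability", "conc_mg_l", "conc_um"),
                    names(profile))[1]
  if (is.na(vcol)) stop("no value column found", call. = FALSE)
  unit <- switch(vcol, viability = "%", conc_mg_l = "mg/L",
                 conc_um = "uM")
  write.csv(data.frame(series = series, time_h = profile$time_h,
                       value = profile[[vcol]], unit = unit),
            path, row.names = FALSE)
  invisible(path)
}
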