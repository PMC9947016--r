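#' Degradation parameters for DOX and DEX in culture medium
#'
#' First-order degradation rate constants describing the loss of
#' doxorubicin and dexrazoxane from cell culture medium at 37 degrees C.
#'
#' @param kdeg_dox First-order degradation rate constant for DOX (1/h).
#' @param kdeg_dex First-order degradation rate constant for DEX (1/h).
#' @return An object of class `degradation_params`.
#' @examples
#' degradation_params(0.022, 0.054)
#' @export
degradation_params <- function(kdeg_dox, kdeg_dex) {
  stopifnot(is.numeric(kdeg_dox), is.numeric(kdeg_dex),
            length(kdeg_dox) == 1L, length(kdeg_dex) == 1L)
  if (kdeg_dox < 0 || kdeg_dex < 0)
    stop("degradation rate constants must be >= 0", call. = FALSE)
  structure(list(kdeg_dox = kdeg_dox, kdeg_dex = kdeg_dex),
            class = "degradation_params")
}

#' Reference degradation rates
#'
#' Degradation rate constants estimated for DOX (0.022 1/h) and DEX
#' (0.054 1/h) in cell culture medium; DEX degrades roughly 2.5-fold
#' faster than DOX.
#'
#' @return A [degradation_params()] object.
#' @export
default_degradation_params <- function() degradation_params(0.022, 0.054)

.td_par_names <- c("kg", "r0", "s_dox", "s_dex", "kmax_dox", "kc50_dox",
                   "ktr_dox", "imax_dexi", "ic50_dexi")

#' Cellular toxicodynamic parameters
#'
#' The nine parameters of the cellular TD model for AC16 cardiomyocytes.
#' The transit delay is parameterized by the transit rate constant
#' `ktr_dox` (1/h), the reciprocal of the mean transit time per
#' compartment.
#'
#' @param kg First-order growth rate constant (1/h).
#' @param r0 Baseline viability at time zero (%).
#' @param s_dox Linear growth-inhibition slope for DOX (1/uM).
#' @param s_dex Linear growth-inhibition slope for DEX (1/uM).
#' @param kmax_dox Maximal killing rate constant of DOX (1/h).
#' @param kc50_dox DOX concentration giving half-maximal killing (uM).
#' @param ktr_dox Transit rate constant of the three-compartment death
#'   delay chain (1/h).
#' @param imax_dexi Maximal inhibition rate constant of DEX on DOX's
#'   death stimulation (1/h).
#' @param ic50_dexi DEX concentration giving half-maximal inhibition (uM).
#' @return An object of class `td_params` (a named numeric vector).
#' @seealso [td_params_ac16()] for the reference estimates,
#'   [mean_transit_time()] for the `ktr_dox` <-> mean-transit-time
#'   conversion.
#' @export
td_params <- function(kg, r0, s_dox, s_dex, kmax_dox, kc50_dox,
                      ktr_dox, imax_dexi, ic50_dexi) {
  p <- c(kg = kg, r0 = r0, s_dox = s_dox, s_dex = s_dex,
         kmax_dox = kmax_dox, kc50_dox = kc50_dox, ktr_dox = ktr_dox,
         imax_dexi = imax_dexi, ic50_dexi = ic50_dexi)
  validate_td_params(p)
  structure(p, class = "td_params")
}

validate_td_params <- function(p) {
  if (!all(.td_par_names %in% names(p)))
    stop("missing TD parameters: ",
         paste(setdiff(.td_par_names, names(p)), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all TD parameters must be finite and strictly positive",
         call. = FALSE)
  if (p[["r0"]] > 150)
    stop("r0 must lie in (0, 150] percent", call. = FALSE)
  invisible(p)
}

#' Reference TD parameter estimates for AC16 cardiomyocytes
#'
#' The reference cellular TD parameter set for AC16 human cardiomyocytes:
#' growth rate 0.0115 1/h, baseline viability 101%, growth-inhibition
#' slopes 0.167 (DOX) and 0.00968 (DEX) 1/uM, maximal kill rate
#' 0.0697 1/h with KC50 0.107 uM, transit rate constant 0.126 1/h
#' (mean transit time about 8 h), and DEX interaction Imax 0.0625 1/h
#' with IC50 39 uM.
#'
#' @return A [td_params()] object.
#' @export
td_params_ac16 <- function() {
  td_params(kg = 0.0115, r0 = 101, s_dox = 0.167, s_dex = 0.00968,
            kmax_dox = 0.0697, kc50_dox = 0.107, ktr_dox = 0.126,
            imax_dexi = 0.0625, ic50_dexi = 39)
}

#' Mean transit time of the death-delay chain
#'
#' Converts the transit rate constant to the mean transit time per
#' compartment (h), `1 / ktr_dox`.
#'
#' @param p A [td_params()] object, or a transit rate constant (1/h).
#' @return Mean transit time per compartment (h).
#' @examples
#' mean_transit_time(td_params_ac16())  # about 8 h
#' @export
mean_transit_time <- function(p) {
  ktr <- if (inherits(p, "td_params")) p[["ktr_dox"]] else as.numeric(p)
  stopifnot(ktr > 0)
  1 / ktr
}

#' Clinical DOX pharmacokinetic parameters (3-compartment model)
#'
#' Linear mammillary three-compartment disposition parameters for
#' doxorubicin, scaled to a 1.8 m2 subject: clearance and central volume
#' plus two peripheral compartments with inter-compartmental clearances.
#'
#' @param cl Clearance from the central compartment (L/h).
#' @param v Central volume of distribution (L).
#' @param q2,v2 Inter-compartmental clearance (L/h) and volume (L) of
#'   the first peripheral compartment.
#' @param q3,v3 Inter-compartmental clearance (L/h) and volume (L) of
#'   the second peripheral compartment.
#' @return An object of class `pk_params_dox`.
#' @export
pk_params_dox <- function(cl, v, q2, v2, q3, v3) {
  p <- c(cl = cl, v = v, q2 = q2, v2 = v2, q3 = q3, v3 = v3)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all DOX PK parameters must be finite and strictly positive",
         call. = FALSE)
  structure(as.list(p), class = "pk_params_dox")
}

#' Reference clinical DOX PK parameters
#'
#' Published population-typical three-compartment values for a 1.8 m2
#' adult: CL 53.3 L/h, V 17.7 L, Q2 58.7 L/h, V2 1830 L, Q3 21.8 L/h,
#' V3 71.6 L. The very large shallow peripheral volume produces the
#' long terminal phase characteristic of DOX.
#'
#' @return A [pk_params_dox()] object.
#' @export
pk_params_dox_default <- function() {
  pk_params_dox(cl = 53.3, v = 17.7, q2 = 58.7, v2 = 1830, q3 = 21.8,
                v3 = 71.6)
}

#' Clinical DEX pharmacokinetic parameters (2-compartment model)
#'
#' Linear two-compartment disposition for dexrazoxane parameterized by
#' micro rate constants, with elimination from the central compartment.
#'
#' @param kel First-order elimination rate constant (1/h).
#' @param k12 Central-to-peripheral distribution rate constant (1/h).
#' @param k21 Peripheral-to-central distribution rate constant (1/h).
#' @param v Central volume of distribution (L).
#' @return An object of class `pk_params_dex`.
#' @export
pk_params_dex <- function(kel, k12, k21, v) {
  p <- c(kel = kel, k12 = k12, k21 = k21, v = v)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all DEX PK parameters must be finite and strictly positive",
         call. = FALSE)
  structure(as.list(p), class = "pk_params_dex")
}

#' Reference clinical DEX PK parameters
#'
#' Two-compartment values fitted to phase-I serum data over the
#' 50-2500 mg/m2 infusion range: kel, k12 and k21 all 1 1/h and a
#' central volume of 14.6 L (the printed rate constants are used as-is).
#'
#' @return A [pk_params_dex()] object.
#' @export
pk_params_dex_default <- function() {
  pk_params_dex(kel = 1, k12 = 1, k21 = 1, v = 14.6)
}

#' Molar masses used for the plasma-to-medium unit bridge
#'
#' Free-base molar masses used to convert plasma concentrations (mg/L)
#' to the micromolar scale of the in vitro TD model: DOX 543.52 g/mol,
#' DEX 268.27 g/mol.
#'
#' @format Named numeric vector (g/mol).
#' @export
molar_masses <- c(DOX = 543.52, DEX = 268.27)

#' Serialize model parameters to JSON
#'
#' Writes a parameter object with explicit unit annotations so that
#' files are self-describing.
#'
#' @param p A `td_params`, `degradation_params`, `pk_params_dox` or
#'   `pk_params_dex` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(p, path) {
  units <- switch(class(p)[1],
    td_params = c(kg = "1/h", r0 = "%", s_dox = "1/uM", s_dex = "1/uM",
                  kmax_dox = "1/h", kc50_dox = "uM", ktr_dox = "1/h",
                  imax_dexi = "1/h", ic50_dexi = "uM"),
    degradation_params = c(kdeg_dox = "1/h", kdeg_dex = "1/h"),
    pk_params_dox = c(cl = "L/h", v = "L", q2 = "L/h", v2 = "L",
                      q3 = "L/h", v3 = "L"),
    pk_params_dex = c(kel = "1/h", k12 = "1/h", k21 = "1/h", v = "L"),
    stop("unsupported parameter class: ", class(p)[1], call. = FALSE))
  obj <- list(class = class(p)[1],
              values = as.list(setNames(as.numeric(unlist(p)[names(units)]),
                                        names(units))),
              units = as.list(units))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path Path to a file written by [write_params_json()].
#' @return The parameter object of the class recorded in the file.
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- as.list(obj$values)
  switch(obj$class,
    td_params = do.call(td_params, v[.td_par_names]),
    degradation_params = do.call(degradation_params, v),
    pk_params_dox = do.call(pk_params_dox, v),
    pk_params_dex = do.call(pk_params_dex, v),
    stop("unknown parameter class in file: ", obj$class, call. = FALSE))
}
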