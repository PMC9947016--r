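# Solver contract shared by all simulators: stiff-capable lsoda, tight
# tolerances because downstream AUEC contrasts between regimens are small.
.rtol <- 1e-8
.atol <- 1e-10

#' Drug concentration under first-order degradation
#'
#' Closed-form concentration in culture medium, `c0 * exp(-kdeg * t)`.
#' Degradation rates are assumed concentration-independent and unaffected
#' by the presence of the other drug.
#'
#' @param c0 Initial concentration (uM).
#' @param kdeg First-order degradation rate constant (1/h).
#' @param t Time (h); may be a vector.
#' @return Concentration (uM) at each `t`.
#' @examples
#' conc_at(0.5, 0.022, c(0, 24, 72))
#' @export
conc_at <- function(c0, kdeg, t) {
  if (any(c0 < 0) || any(kdeg < 0) || any(t < 0))
    stop("conc_at() requires c0, kdeg and t all >= 0", call. = FALSE)
  c0 * exp(-kdeg * t)
}

#' DOX death-stimulation rate (Hill function)
#'
#' Saturable killing rate `kmax_dox * C / (kc50_dox + C)`; monotone in
#' concentration and bounded by `kmax_dox`.
#'
#' @param c_dox DOX concentration (uM); may be a vector.
#' @param p A [td_params()] object.
#' @return Killing rate (1/h).
#' @export
dox_kill_rate <- function(c_dox, p) {
  stopifnot(all(c_dox >= 0))
  p[["kmax_dox"]] * c_dox / (p[["kc50_dox"]] + c_dox)
}

#' DEX inhibition rate on DOX death stimulation (Hill function)
#'
#' Saturable inhibition `imax_dexi * C / (ic50_dexi + C)` of the DOX
#' kill signal entering the transit chain.
#'
#' @param c_dex DEX concentration (uM); may be a vector.
#' @param p A [td_params()] object.
#' @return Inhibition rate (1/h).
#' @export
dex_inhibition_rate <- function(c_dex, p) {
  stopifnot(all(c_dex >= 0))
  p[["imax_dexi"]] * c_dex / (p[["ic50_dexi"]] + c_dex)
}

#' Untreated (control) viability
#'
#' Exponential growth of untreated AC16 cells, `r0 * exp(kg * t)`.
#'
#' @param t Time (h); may be a vector.
#' @param p A [td_params()] object.
#' @return Viability (%).
#' @export
control_viability <- function(t, p) {
  stopifnot(all(t >= 0))
  p[["r0"]] * exp(p[["kg"]] * t)
}

#' Right-hand side of the cellular TD model
#'
#' Derivatives of viability `r` and the three transit-compartment kill
#' signals `k1..k3` at given drug concentrations. The kill chain is fed
#' by the net signal `dox_kill_rate(c_dox) - dex_inhibition_rate(c_dex)`,
#' taken literally by default; with `clamp_net_kill = TRUE` the chain
#' input is floored at zero, so an excess of DEX can at most abolish --
#' never reverse -- the DOX death stimulus. Growth is inhibited linearly
#' by both drugs: `(1 - (s_dox*c_dox + s_dex*c_dex)) * kg * r - k3 * r`.
#'
#' @param state Named numeric vector `c(r, k1, k2, k3)`: viability (%)
#'   and the transit kill signals (1/h).
#' @param c_dox,c_dex Current drug concentrations (uM).
#' @param p A [td_params()] object.
#' @param clamp_net_kill Floor the kill-chain input at zero?
#' @return Named numeric vector of derivatives `d(state)/dt`.
#' @examples
#' td_rhs(c(r = 101, k1 = 0, k2 = 0, k3 = 0), 0, 0, td_params_ac16())
#' @export
td_rhs <- function(state, c_dox, c_dex, p, clamp_net_kill = FALSE) {
  stopifnot(c_dox >= 0, c_dex >= 0)
  r <- state[["r"]]; k1 <- state[["k1"]]; k2 <- state[["k2"]]
  k3 <- state[["k3"]]
  u <- dox_kill_rate(c_dox, p) - dex_inhibition_rate(c_dex, p)
  if (clamp_net_kill) u <- max(u, 0)
  growth <- (1 - (p[["s_dox"]] * c_dox + p[["s_dex"]] * c_dex)) * p[["kg"]]
  ktr <- p[["ktr_dox"]]
  c(r = growth * r - k3 * r,
    k1 = ktr * (u - k1),
    k2 = ktr * (k1 - k2),
    k3 = ktr * (k2 - k3))
}

#' In vitro exposure condition
#'
#' One well condition of the viability experiment: initial DOX and DEX
#' concentrations, observation times and replicate count.
#'
#' @param c_dox0 Initial DOX concentration (uM).
#' @param c_dex0 Initial DEX concentration (uM).
#' @param timepoints Observation times (h), sorted, starting at 0.
#' @param replicates Number of replicate wells.
#' @return An object of class `invitro_condition`.
#' @export
invitro_condition <- function(c_dox0, c_dex0,
                              timepoints = c(0, 12, 24, 48, 72),
                              replicates = 3L) {
  if (c_dox0 < 0 || c_dex0 < 0)
    stop("initial concentrations must be >= 0", call. = FALSE)
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1] != 0)
    stop("timepoints must be strictly increasing and start at 0",
         call. = FALSE)
  structure(list(c_dox0 = c_dox0, c_dex0 = c_dex0,
                 timepoints = timepoints,
                 replicates = as.integer(replicates)),
            class = "invitro_condition")
}

# Stacked forward solve of all conditions at once: one lsoda call on a
# block system (viability + 3 kill states per condition). Conditions
# without DOX use the single-agent DEX arm, i.e. no kill-chain input --
# the DEX interaction inhibits the DOX death signal and has nothing to
# act on in its absence.
predict_viability_matrix <- function(cond, p, d, times,
                                     clamp_net_kill = FALSE) {
  nc <- nrow(cond)
  cd0 <- cond$c_dox0; cx0 <- cond$c_dex0
  has_dox <- as.numeric(cd0 > 0)
  kdd <- d$kdeg_dox; kdx <- d$kdeg_dex
  kg <- p[["kg"]]; sdo <- p[["s_dox"]]; sde <- p[["s_dex"]]
  kmax <- p[["kmax_dox"]]; kc50 <- p[["kc50_dox"]]; ktr <- p[["ktr_dox"]]
  imax <- p[["imax_dexi"]]; ic50 <- p[["ic50_dexi"]]
  rhs <- function(t, y, parms) {
    r <- y[1:nc]; k1 <- y[nc + 1:nc]; k2 <- y[2 * nc + 1:nc]
    k3 <- y[3 * nc + 1:nc]
    cdt <- cd0 * exp(-kdd * t)
    cxt <- cx0 * exp(-kdx * t)
    u <- kmax * cdt / (kc50 + cdt) -
      has_dox * imax * cxt / (ic50 + cxt)
    if (clamp_net_kill) u <- pmax(u, 0)
    list(c((1 - (sdo * cdt + sde * cxt)) * kg * r - k3 * r,
           ktr * (u - k1), ktr * (k1 - k2), ktr * (k2 - k3)))
  }
  t0_extra <- times[1] != 0
  tt <- if (t0_extra) c(0, times) else times
  y0 <- c(rep(p[["r0"]], nc), rep(0, 3 * nc))
  out <- deSolve::lsoda(y0, tt, rhs, parms = NULL,
                        rtol = .rtol, atol = .atol)
  if (attr(out, "istate")[1] < 0)
    stop("TD integration failed (lsoda istate ",
         attr(out, "istate")[1], ")", call. = FALSE)
  m <- out[, 1 + 1:nc, drop = FALSE]
  if (t0_extra) m <- m[-1, , drop = FALSE]
  dimnames(m) <- NULL
  m  # times x conditions
}

#' Simulate an in vitro viability time course
#'
#' Integrates the TD model for one exposure condition, with medium drug
#' concentrations given by the closed-form degradation model (evaluated
#' inside the right-hand side, not co-integrated). A condition with no
#' DOX follows the single-agent DEX arm (growth inhibition only, no
#' death-stimulation chain).
#'
#' @param cond An [invitro_condition()].
#' @param p A [td_params()] object.
#' @param d A [degradation_params()] object.
#' @param out_times Output time grid (h); defaults to the condition's
#'   timepoints.
#' @param clamp_net_kill Floor the kill-chain input at zero (see
#'   [td_rhs()]).
#' @return A data frame with columns `time_h` and `viability`.
#' @examples
#' simulate_invitro(invitro_condition(0.5, 0), td_params_ac16(),
#'                  default_degradation_params())
#' @export
simulate_invitro <- function(cond, p, d, out_times = cond$timepoints,
                             clamp_net_kill = FALSE) {
  stopifnot(inherits(cond, "invitro_condition"))
  m <- predict_viability_matrix(
    data.frame(c_dox0 = cond$c_dox0, c_dex0 = cond$c_dex0),
    p, d, out_times, clamp_net_kill)
  data.frame(time_h = out_times, viability = m[, 1])
}

# Piecewise integration of a linear mammillary system with piecewise-
# constant infusion input into compartment 1. A is the (constant)
# transfer matrix; events is a data.frame(amount_mg, start_h, duration_h).
# Integrates segment-by-segment between infusion boundaries so short
# infusions are never stepped over; overlapping infusion rates sum.
simulate_linear_pk <- function(events, A, grid) {
  n <- nrow(A)
  starts <- events$start_h
  ends <- events$start_h + events$duration_h
  rates <- ifelse(events$duration_h > 0,
                  events$amount_mg / events$duration_h, 0)
  t0 <- grid[1]; t1 <- grid[length(grid)]
  bounds <- sort(unique(c(t0, t1, starts[starts > t0 & starts < t1],
                          ends[ends > t0 & ends < t1])))
  rhs <- function(t, y, parms) list(drop(A %*% y) + parms)
  y <- rep(0, n)
  amounts <- matrix(NA_real_, length(grid), n)
  if (grid[1] == t0) amounts[1, ] <- y
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    mid <- (a + b) / 2
    rate_in <- sum(rates[starts <= mid & ends > mid])
    inp <- c(rate_in, rep(0, n - 1))
    idx <- which(grid > a & grid <= b)
    tt <- unique(c(a, grid[idx], b))
    out <- deSolve::lsoda(y, tt, rhs, parms = inp,
                          rtol = .rtol, atol = .atol)
    if (attr(out, "istate")[1] < 0)
      stop("PK integration failed on segment [", a, ", ", b, "] h",
           call. = FALSE)
    y <- out[nrow(out), -1]
    if (length(idx))
      amounts[idx, ] <- out[match(grid[idx], out[, 1]), -1, drop = FALSE]
  }
  amounts
}

check_regimen_drug <- function(regimen, drug) {
  stopifnot(inherits(regimen, "regimen"))
  if (nrow(regimen$events) && !all(regimen$events$drug == drug))
    stop("regimen contains non-", drug, " events", call. = FALSE)
  regimen$events
}

#' Simulate clinical DOX plasma concentrations
#'
#' Linear mammillary three-compartment model with infusion input to and
#' elimination from the central compartment; the returned concentration
#' is central amount / central volume. Superposition holds across dose
#' events and overlapping infusions are summed.
#'
#' @param regimen A [build_regimen()] object containing only DOX events.
#' @param p A [pk_params_dox()] object.
#' @param grid Output time grid (h); defaults to 0.25-h steps over the
#'   regimen horizon.
#' @return A data frame with columns `time_h` and `conc_mg_l`, with
#'   attribute `drug = "DOX"`.
#' @export
simulate_pk_dox <- function(regimen, p,
                            grid = seq(0, regimen$horizon_h, by = 0.25)) {
  events <- check_regimen_drug(regimen, "DOX")
  amounts <- simulate_linear_pk(events, pk_matrix_dox(p), grid)
  structure(data.frame(time_h = grid, conc_mg_l = amounts[, 1] / p$v),
            drug = "DOX")
}

#' Simulate clinical DEX plasma concentrations
#'
#' Linear two-compartment model with first-order micro rate constants:
#' `dA1/dt = rate(t) - kel*A1 - k12*A1 + k21*A2`,
#' `dA2/dt = k12*A1 - k21*A2`, concentration `C1 = A1/V`.
#'
#' @param regimen A [build_regimen()] object containing only DEX events.
#' @param p A [pk_params_dex()] object.
#' @param grid Output time grid (h).
#' @return A data frame with columns `time_h` and `conc_mg_l`, with
#'   attribute `drug = "DEX"`.
#' @export
simulate_pk_dex <- function(regimen, p,
                            grid = seq(0, regimen$horizon_h, by = 0.25)) {
  events <- check_regimen_drug(regimen, "DEX")
  amounts <- simulate_linear_pk(events, pk_matrix_dex(p), grid)
  structure(data.frame(time_h = grid, conc_mg_l = amounts[, 1] / p$v),
            drug = "DEX")
}

pk_matrix_dox <- function(p) {
  k10 <- p$cl / p$v; k12 <- p$q2 / p$v; k21 <- p$q2 / p$v2
  k13 <- p$q3 / p$v; k31 <- p$q3 / p$v3
  matrix(c(-(k10 + k12 + k13), k21, k31,
           k12, -k21, 0,
           k13, 0, -k31), 3, 3, byrow = TRUE)
}

pk_matrix_dex <- function(p) {
  matrix(c(-(p$kel + p$k12), p$k21,
           p$k12, -p$k21), 2, 2, byrow = TRUE)
}
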