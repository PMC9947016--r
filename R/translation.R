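# In vitro-in vivo translation: clinical infusion regimens drive the
# compartmental PK models; plasma concentrations (converted to uM) then
# drive the cellular TD model, and regimens are scored by the area under
# the viability-time curve (AUEC).

#' Build an intravenous infusion regimen
#'
#' Repeated constant-rate infusions of one drug: `n_doses` events at
#' `start = k * interval_h`, each of `dose_per_m2 * bsa` mg over
#' `duration_h` hours.
#'
#' @param drug `"DOX"` or `"DEX"`.
#' @param dose_per_m2 Dose per administration (mg/m2).
#' @param bsa Body surface area (m2).
#' @param interval_h Dosing interval (h); 504 for Q3W, 168 for Q1W.
#' @param n_doses Number of administrations.
#' @param duration_h Infusion duration (h); 0.25 for a 15-min infusion.
#' @param start_h Start of the first infusion (h).
#' @param horizon_h Simulation horizon (h); defaults to
#'   `start_h + n_doses * interval_h` (end of the last cycle).
#' @return An object of class `regimen`.
#' @examples
#' build_regimen("DOX", 50, bsa = 1.8, interval_h = 504, n_doses = 3)
#' @export
build_regimen <- function(drug = c("DOX", "DEX"), dose_per_m2, bsa = 1.8,
                          interval_h, n_doses, duration_h = 0.25,
                          start_h = 0, horizon_h = NULL) {
  drug <- match.arg(drug)
  stopifnot(dose_per_m2 >= 0, bsa > 0, interval_h > 0, n_doses >= 1,
            duration_h > 0, start_h >= 0)
  starts <- start_h + (seq_len(n_doses) - 1) * interval_h
  if (is.null(horizon_h)) horizon_h <- start_h + n_doses * interval_h
  events <- data.frame(drug = drug, amount_mg = dose_per_m2 * bsa,
                       start_h = starts, duration_h = duration_h)
  if (horizon_h < max(starts + duration_h))
    stop("horizon ends before the last infusion", call. = FALSE)
  structure(list(events = events, bsa = bsa, horizon_h = horizon_h),
            class = "regimen")
}

#' Shift all dose events of a regimen in time
#'
#' @param regimen A [build_regimen()] object.
#' @param offset_h Time offset (h) added to every event start and to the
#'   horizon.
#' @return The shifted `regimen`.
#' @export
shift_regimen <- function(regimen, offset_h) {
  stopifnot(inherits(regimen, "regimen"))
  regimen$events$start_h <- regimen$events$start_h + offset_h
  regimen$horizon_h <- regimen$horizon_h + offset_h
  regimen
}

#' Convert a mass concentration to micromolar
#'
#' `conc * 1000 / molar_mass`; bridges plasma PK output (mg/L) to the
#' micromolar scale of the in vitro TD model. Total plasma concentration
#' is assumed to drive the TD model (no protein-binding correction).
#'
#' @param conc Concentration (mg/L); may be a vector.
#' @param molar_mass Molar mass (g/mol); see [molar_masses].
#' @return Concentration (uM).
#' @examples
#' to_micromolar(1, molar_masses[["DOX"]])
#' @export
to_micromolar <- function(conc, molar_mass) {
  if (molar_mass <= 0) stop("molar_mass must be > 0", call. = FALSE)
  conc * 1000 / molar_mass
}

#' Simulate the viability time course of one (virtual) subject
#'
#' Simulates plasma PK for both regimens, converts concentrations to
#' uM, and drives the combination TD model from an initial viability of
#' 100% (kill states zero). Clinical simulations default to the clamped
#' net-kill mode because plasma DEX concentrations far exceed the in
#' vitro interaction regime.
#'
#' @param reg_dox DOX [build_regimen()], or `NULL` for no DOX.
#' @param reg_dex DEX [build_regimen()], or `NULL` for no DEX.
#' @param pk_dox A [pk_params_dox()] object.
#' @param pk_dex A [pk_params_dex()] object.
#' @param td A [td_params()] object.
#' @param r0 Initial viability (%); the clinical default is 100.
#' @param clamp_net_kill Floor the kill-chain input at zero (default on
#'   for clinical simulation; see [td_rhs()]).
#' @param grid_step Output grid spacing (h).
#' @return Data frame with columns `time_h` and `viability`; the PK
#'   profiles are attached as attribute `pk`.
#' @export
simulate_subject <- function(reg_dox, reg_dex,
                             pk_dox = pk_params_dox_default(),
                             pk_dex = pk_params_dex_default(),
                             td = td_params_ac16(), r0 = 100,
                             clamp_net_kill = TRUE, grid_step = 0.25) {
  horizon <- max(if (!is.null(reg_dox)) reg_dox$horizon_h else 0,
                 if (!is.null(reg_dex)) reg_dex$horizon_h else 0)
  if (horizon <= 0) stop("at least one regimen required", call. = FALSE)
  grid <- seq(0, horizon, by = grid_step)
  if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
  ev_dox <- if (!is.null(reg_dox)) check_regimen_drug(reg_dox, "DOX")
            else data.frame(amount_mg = numeric(0), start_h = numeric(0),
                            duration_h = numeric(0))
  ev_dex <- if (!is.null(reg_dex)) check_regimen_drug(reg_dex, "DEX")
            else data.frame(amount_mg = numeric(0), start_h = numeric(0),
                            duration_h = numeric(0))

  Ad <- pk_matrix_dox(pk_dox); Ax <- pk_matrix_dex(pk_dex)
  fd <- 1000 / (molar_masses[["DOX"]] * pk_dox$v)  # amount mg -> uM
  fx <- 1000 / (molar_masses[["DEX"]] * pk_dex$v)
  kg <- td[["kg"]]; sdo <- td[["s_dox"]]; sde <- td[["s_dex"]]
  kmax <- td[["kmax_dox"]]; kc50 <- td[["kc50_dox"]]
  ktr <- td[["ktr_dox"]]; imax <- td[["imax_dexi"]]
  ic50 <- td[["ic50_dexi"]]

  # PK amounts and TD states co-integrated piecewise between infusion
  # boundaries: the TD forcing is exact, not an interpolated profile.
  rhs <- function(t, y, rates) {
    ad <- y[1:3]; ax <- y[4:5]
    cd <- ad[1] * fd; cx <- ax[1] * fx
    u <- kmax * cd / (kc50 + cd) - imax * cx / (ic50 + cx)
    if (clamp_net_kill) u <- max(u, 0)
    list(c(drop(Ad %*% ad) + c(rates[1], 0, 0),
           drop(Ax %*% ax) + c(rates[2], 0),
           (1 - (sdo * cd + sde * cx)) * kg * y[6] - y[9] * y[6],
           ktr * (u - y[7]), ktr * (y[7] - y[8]), ktr * (y[8] - y[9])))
  }
  rate_at <- function(ev, mid) {
    if (!nrow(ev)) return(0)
    on <- ev$start_h <= mid & (ev$start_h + ev$duration_h) > mid
    sum(ev$amount_mg[on] / ev$duration_h[on])
  }
  bnd <- sort(unique(c(0, horizon,
                       ev_dox$start_h, ev_dox$start_h + ev_dox$duration_h,
                       ev_dex$start_h, ev_dex$start_h + ev_dex$duration_h)))
  bnd <- bnd[bnd >= 0 & bnd <= horizon]
  y <- c(0, 0, 0, 0, 0, r0, 0, 0, 0)
  states <- matrix(NA_real_, length(grid), 9)
  states[1, ] <- y
  for (i in seq_len(length(bnd) - 1)) {
    a <- bnd[i]; b <- bnd[i + 1]
    rates <- c(rate_at(ev_dox, (a + b) / 2), rate_at(ev_dex, (a + b) / 2))
    idx <- which(grid > a & grid <= b)
    tt <- unique(c(a, grid[idx], b))
    out <- deSolve::lsoda(y, tt, rhs, rates, rtol = 1e-8, atol = 1e-10)
    if (attr(out, "istate")[1] < 0)
      stop("subject simulation failed on segment [", a, ", ", b, "] h",
           call. = FALSE)
    y <- out[nrow(out), -1]
    if (length(idx))
      states[idx, ] <- out[match(grid[idx], out[, 1]), -1, drop = FALSE]
  }
  res <- data.frame(time_h = grid, viability = states[, 6])
  attr(res, "pk") <- list(
    dox = if (!is.null(reg_dox))
      data.frame(time_h = grid, conc_mg_l = states[, 1] / pk_dox$v),
    dex = if (!is.null(reg_dex))
      data.frame(time_h = grid, conc_mg_l = states[, 4] / pk_dex$v))
  res
}

#' Virtual population specification
#'
#' @param n_subjects Number of virtual subjects.
#' @param iiv_cv Inter-individual variability as a lognormal coefficient
#'   of variation (fraction) applied to the TD parameters.
#' @param seed Integer seed.
#' @param targets Names of TD parameters receiving variability
#'   (default: all nine).
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 500L, iiv_cv = 0.10, seed = 1L,
                            targets = .td_par_names) {
  stopifnot(n_subjects >= 1, iiv_cv >= 0,
            all(targets %in% .td_par_names))
  structure(list(n_subjects = as.integer(n_subjects), iiv_cv = iiv_cv,
                 seed = as.integer(seed), targets = targets),
            class = "population_spec")
}

#' Draw individual TD parameter sets for a virtual population
#'
#' Lognormal sampling with the exp-scale median equal to the typical
#' value and `sdlog = sqrt(log(1 + cv^2))`, so the empirical CV of each
#' sampled parameter matches `iiv_cv`.
#'
#' @param spec A [population_spec()] object.
#' @param td Typical-value [td_params()].
#' @return Matrix (`n_subjects` x 9) of individual parameter values.
#' @export
draw_population_params <- function(spec, td = td_params_ac16()) {
  stopifnot(inherits(spec, "population_spec"))
  typ <- unclass(td)[.td_par_names]
  sdlog <- sqrt(log(1 + spec$iiv_cv^2))
  with_seed(spec$seed, {
    m <- matrix(rep(typ, each = spec$n_subjects), nrow = spec$n_subjects,
                dimnames = list(NULL, .td_par_names))
    for (nm in spec$targets)
      m[, nm] <- m[, nm] * exp(rnorm(spec$n_subjects, 0, sdlog))
    m
  })
}

#' Simulate a virtual population
#'
#' Per-subject TD parameters are drawn with [draw_population_params()];
#' PK parameters are held at their typical values (variability is
#' applied to the TD parameters only). Baseline viability uses 100% as
#' the typical value, perturbed like the other parameters when `r0` is
#' among the targets.
#'
#' @param spec A [population_spec()] object.
#' @param reg_dox,reg_dex Regimens as in [simulate_subject()].
#' @param pk_dox,pk_dex,td Typical-value parameter objects.
#' @param clamp_net_kill,grid_step Passed to [simulate_subject()].
#' @return A list with `time_h`, `profiles` (time x subjects matrix),
#'   `quantiles` (data frame with 5/50/95% bands) and `params`.
#' @export
population_simulate <- function(spec, reg_dox, reg_dex,
                                pk_dox = pk_params_dox_default(),
                                pk_dex = pk_params_dex_default(),
                                td = td_params_ac16(),
                                clamp_net_kill = TRUE, grid_step = 0.25) {
  td_clin <- td
  td_clin[["r0"]] <- 100
  pars <- draw_population_params(spec, td_clin)
  profiles <- NULL
  for (i in seq_len(spec$n_subjects)) {
    td_i <- structure(pars[i, ], class = "td_params")
    out <- simulate_subject(reg_dox, reg_dex, pk_dox, pk_dex, td_i,
                            r0 = td_i[["r0"]],
                            clamp_net_kill = clamp_net_kill,
                            grid_step = grid_step)
    if (is.null(profiles))
      profiles <- matrix(NA_real_, nrow(out), spec$n_subjects)
    profiles[, i] <- out$viability
  }
  time_h <- out$time_h
  qs <- t(apply(profiles, 1, quantile, probs = c(0.05, 0.5, 0.95)))
  list(time_h = time_h, profiles = profiles,
       quantiles = data.frame(time_h = time_h, q05 = qs[, 1],
                              q50 = qs[, 2], q95 = qs[, 3]),
       params = pars)
}

#' Area under the effect (viability) curve
#'
#' Trapezoidal integral of a viability profile over a time window,
#' in %*h. Window boundaries not on the grid are handled by linear
#' interpolation.
#'
#' @param profile Data frame with `time_h` and `viability` (as returned
#'   by [simulate_subject()]).
#' @param t_start,t_end Integration window (h); defaults to the full
#'   profile.
#' @return AUEC (%*h).
#' @examples
#' prof <- data.frame(time_h = 0:504, viability = 100)
#' auec(prof)  # 50400
#' @export
auec <- function(profile, t_start = min(profile$time_h),
                 t_end = max(profile$time_h)) {
  tt <- profile$time_h; v <- profile$viability
  if (t_start < min(tt) || t_end > max(tt) || t_start >= t_end)
    stop("AUEC window must lie within the profile", call. = FALSE)
  sel <- tt > t_start & tt < t_end
  x <- c(t_start, tt[sel], t_end)
  y <- c(approx(tt, v, t_start)$y, v[sel], approx(tt, v, t_end)$y)
  trapz(x, y)
}

#' Scan DEX:DOX dose ratios for maximal cardioprotection
#'
#' For a fixed DOX regimen, co-administers DEX at each dose ratio
#' (simultaneous 15-min infusions) and computes the protection metric
#' `AUEC(DOX+DEX) / AUEC(DOX)` over the full horizon. The reported
#' optimum is the smallest ratio whose AUEC ratio is within `tie_tol`
#' (default 1%) of the maximum, since neighbouring ratios on the
#' saturating part of the interaction are practically equivalent. The
#' table also reports the metric under the literal (unclamped) net-kill
#' equation so the clamping choice is always visible.
#'
#' @param dox_dose_per_m2 DOX dose (mg/m2) per administration.
#' @param ratios DEX:DOX dose ratios to scan.
#' @param cycles Number of dosing cycles.
#' @param interval_h Dosing interval (h); 504 for Q3W.
#' @param bsa Body surface area (m2).
#' @param mode `"typical"` (deterministic typical subject) or
#'   `"population"` (median over a virtual population).
#' @param td,pk_dox,pk_dex Parameter objects.
#' @param clamp_net_kill Net-kill mode for the headline metric.
#' @param include_literal Also compute the unclamped metric (typical
#'   mode only)?
#' @param pop_spec A [population_spec()] for `mode = "population"`.
#' @param tie_tol Relative tie tolerance for the optimum rule.
#' @param grid_step Output grid spacing (h).
#' @return A list of class `ratio_scan`: `table` (one row per ratio),
#'   `optimum`, `auec_dox`, `window_h`, `mode`, `clamp_net_kill`.
#' @export
scan_dose_ratios <- function(dox_dose_per_m2 = 50,
                             ratios = c(0, 1, 5, 10, 20, 50),
                             cycles = 3, interval_h = 504, bsa = 1.8,
                             mode = c("typical", "population"),
                             td = td_params_ac16(),
                             pk_dox = pk_params_dox_default(),
                             pk_dex = pk_params_dex_default(),
                             clamp_net_kill = TRUE,
                             include_literal = TRUE,
                             pop_spec = population_spec(),
                             tie_tol = 0.01, grid_step = 0.25) {
  mode <- match.arg(mode)
  stopifnot(all(ratios >= 0))
  reg_dox <- build_regimen("DOX", dox_dose_per_m2, bsa = bsa,
                           interval_h = interval_h, n_doses = cycles)
  one_auec <- function(ratio, clamp) {
    reg_dex <- if (ratio > 0)
      build_regimen("DEX", dox_dose_per_m2 * ratio, bsa = bsa,
                    interval_h = interval_h, n_doses = cycles)
    if (mode == "typical") {
      prof <- simulate_subject(reg_dox, reg_dex, pk_dox, pk_dex, td,
                               clamp_net_kill = clamp,
                               grid_step = grid_step)
      auec(prof)
    } else {
      pop <- population_simulate(pop_spec, reg_dox, reg_dex, pk_dox,
                                 pk_dex, td, clamp_net_kill = clamp,
                                 grid_step = grid_step)
      median(apply(pop$profiles, 2, function(v)
        trapz(pop$time_h, v)))
    }
  }
  auec_dox <- one_auec(0, clamp_net_kill)
  auec_combo <- vapply(ratios, one_auec, numeric(1),
                       clamp = clamp_net_kill)
  tab <- data.frame(ratio = ratios,
                    dex_dose_per_m2 = dox_dose_per_m2 * ratios,
                    auec = auec_combo,
                    auec_ratio = auec_combo / auec_dox)
  if (include_literal && mode == "typical") {
    auec_dox_lit <- one_auec(0, FALSE)
    tab$auec_ratio_literal <- vapply(ratios, one_auec, numeric(1),
                                     clamp = FALSE) / auec_dox_lit
  }
  best <- max(tab$auec_ratio)
  optimum <- min(tab$ratio[tab$auec_ratio >= best * (1 - tie_tol)])
  structure(list(table = tab, optimum = optimum, auec_dox = auec_dox,
                 window_h = c(0, reg_dox$horizon_h), mode = mode,
                 clamp_net_kill = clamp_net_kill, tie_tol = tie_tol),
            class = "ratio_scan")
}

#' @export
print.ratio_scan <- function(x, ...) {
  cat("DEX:DOX dose-ratio scan (", x$mode, " mode, window ",
      x$window_h[1], "-", x$window_h[2], " h, clamp_net_kill = ",
      x$clamp_net_kill, ")\n", sep = "")
  print(x$table, digits = 6, row.names = FALSE)
  cat("optimum (smallest ratio within ", 100 * x$tie_tol,
      "% of the maximum): ", x$optimum, ":1\n", sep = "")
  invisible(x)
}

#' Compare Q3W and dose-fractionated Q1W regimens with and without DEX
#'
#' Simulates four arms at equal cumulative DOX dose -- Q3W alone, Q3W
#' plus DEX, weekly fractionated Q1W alone, Q1W plus DEX (DEX scaled to
#' each administration by `dex_ratio`) -- and reports AUEC per arm over
#' a one-cycle (3-week) and a three-cycle (9-week) window, flagging the
#' best arm per window (ties within `tie_tol`).
#'
#' @param dox_q3w Q3W DOX dose (mg/m2).
#' @param dox_q1w Weekly fractionated DOX dose (mg/m2).
#' @param dex_ratio DEX:DOX dose ratio for the combination arms.
#' @param cycles Number of three-week cycles.
#' @param bsa Body surface area (m2).
#' @param td,pk_dox,pk_dex Parameter objects.
#' @param clamp_net_kill Net-kill mode.
#' @param tie_tol Relative tolerance for tie flagging.
#' @param grid_step Output grid spacing (h).
#' @return A list of class `fractionation_table`: `table` (arm x window
#'   AUEC), `best` (named character, best arm per window), `ties`.
#' @export
compare_fractionation <- function(dox_q3w = 50, dox_q1w = 16.67,
                                  dex_ratio = 10, cycles = 3, bsa = 1.8,
                                  td = td_params_ac16(),
                                  pk_dox = pk_params_dox_default(),
                                  pk_dex = pk_params_dex_default(),
                                  clamp_net_kill = TRUE, tie_tol = 0.01,
                                  grid_step = 0.25) {
  horizon <- cycles * 504
  arms <- list(
    q3w = list(dox = build_regimen("DOX", dox_q3w, bsa = bsa,
                                   interval_h = 504, n_doses = cycles),
               dex = NULL),
    q3w_dex = list(dox = build_regimen("DOX", dox_q3w, bsa = bsa,
                                       interval_h = 504, n_doses = cycles),
                   dex = build_regimen("DEX", dox_q3w * dex_ratio,
                                       bsa = bsa, interval_h = 504,
                                       n_doses = cycles)),
    q1w = list(dox = build_regimen("DOX", dox_q1w, bsa = bsa,
                                   interval_h = 168, n_doses = 3 * cycles),
               dex = NULL),
    q1w_dex = list(dox = build_regimen("DOX", dox_q1w, bsa = bsa,
                                       interval_h = 168,
                                       n_doses = 3 * cycles),
                   dex = build_regimen("DEX", dox_q1w * dex_ratio,
                                       bsa = bsa, interval_h = 168,
                                       n_doses = 3 * cycles)))
  profs <- lapply(arms, function(a)
    simulate_subject(a$dox, a$dex, pk_dox, pk_dex, td,
                     clamp_net_kill = clamp_net_kill,
                     grid_step = grid_step))
  windows <- c(one_cycle = 504, three_cycles = horizon)
  tab <- do.call(rbind, lapply(names(windows), function(w) {
    data.frame(window = w, window_h = windows[[w]], arm = names(arms),
               auec = vapply(profs, auec, numeric(1), t_start = 0,
                             t_end = windows[[w]]))
  }))
  rownames(tab) <- NULL
  best <- vapply(names(windows), function(w) {
    sub <- tab[tab$window == w, ]
    sub$arm[which.max(sub$auec)]
  }, character(1))
  ties <- lapply(names(windows), function(w) {
    sub <- tab[tab$window == w, ]
    sub$arm[sub$auec >= max(sub$auec) * (1 - tie_tol)]
  })
  names(ties) <- names(windows)
  structure(list(table = tab, best = best, ties = ties,
                 tie_tol = tie_tol), class = "fractionation_table")
}

#' @export
print.fractionation_table <- function(x, ...) {
  print(x$table, digits = 6, row.names = FALSE)
  for (w in names(x$best))
    cat(w, ": best arm = ", x$best[[w]],
        if (length(x$ties[[w]]) > 1)
          paste0(" (tied within ", 100 * x$tie_tol, "%: ",
                 paste(x$ties[[w]], collapse = ", "), ")"),
        "\n", sep = "")
  invisible(x)
}
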