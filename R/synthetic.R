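# Seeded generators that emulate the in vitro study design and the
# clinical PK sampling, so that every pipeline stage can be exercised
# without access to the original raw data.

#' Proportional noise specification
#'
#' Multiplicative lognormal noise: each record is multiplied by
#' `exp(N(0, sigma))` with `sigma = log(1 + cv)` (a small-cv
#' approximation that keeps the empirical coefficient of variation of
#' obs/pred close to `cv` while guaranteeing positivity).
#'
#' @param cv Coefficient of variation (fraction, e.g. 0.075).
#' @param seed Integer seed; identical seeds reproduce identical
#'   datasets bit for bit.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.075, seed = 1L) {
  stopifnot(cv >= 0, is.finite(seed))
  structure(list(model = "proportional", cv = cv, seed = as.integer(seed)),
            class = "noise_spec")
}

noise_factors <- function(n, noise) {
  if (noise$cv == 0) return(rep(1, n))
  with_seed(noise$seed, exp(rnorm(n, 0, log(1 + noise$cv))))
}

#' Default in vitro experimental design
#'
#' The viability study design: an untreated control, DOX at 0.5, 1,
#' 2.5, 5 and 10 uM, DEX at 5, 10, 25, 50 and 100 uM, and combinations
#' of 0.5 uM DOX with each DEX level (DEX:DOX ratios 10:1 to 200:1),
#' observed at 0, 12, 24, 48 and 72 h in triplicate. The concentration
#' range endpoints are the study's; the interior levels are a fixed,
#' configurable choice.
#'
#' @param dox_levels,dex_levels Single-agent concentration grids (uM).
#' @param combo_dox DOX concentration used in the combination arm (uM).
#' @param timepoints Observation times (h).
#' @param replicates Replicate wells per condition and time.
#' @return A list of class `design_spec`.
#' @export
default_design <- function(dox_levels = c(0.5, 1, 2.5, 5, 10),
                           dex_levels = c(5, 10, 25, 50, 100),
                           combo_dox = 0.5,
                           timepoints = c(0, 12, 24, 48, 72),
                           replicates = 3L) {
  stopifnot(all(dox_levels > 0), all(dex_levels > 0), combo_dox > 0,
            timepoints[1] == 0, !is.unsorted(timepoints, strictly = TRUE),
            replicates >= 1)
  structure(list(dox_levels = dox_levels, dex_levels = dex_levels,
                 combo_dox = combo_dox, timepoints = timepoints,
                 replicates = as.integer(replicates)),
            class = "design_spec")
}

#' Conditions implied by a design
#'
#' Expands a [default_design()] into its condition table: one control,
#' one row per single-agent level, one per combination level.
#'
#' @param design A `design_spec`.
#' @return Data frame with columns `condition_id`, `c_dox0`, `c_dex0`.
#' @export
design_conditions <- function(design) {
  cond <- rbind(
    data.frame(c_dox0 = 0, c_dex0 = 0),
    data.frame(c_dox0 = design$dox_levels, c_dex0 = 0),
    data.frame(c_dox0 = 0, c_dex0 = design$dex_levels),
    data.frame(c_dox0 = design$combo_dox, c_dex0 = design$dex_levels))
  cls <- condition_class(cond$c_dox0, cond$c_dex0)
  id <- ifelse(cls == "control", "control",
               ifelse(cls == "dox", paste0("DOX_", cond$c_dox0),
                      ifelse(cls == "dex", paste0("DEX_", cond$c_dex0),
                             paste0("DOX_", cond$c_dox0, "_DEX_",
                                    cond$c_dex0))))
  cbind(data.frame(condition_id = id), cond)
}

#' Generate a synthetic viability dataset
#'
#' Simulates every condition of the design with the TD model (medium
#' concentrations from the closed-form degradation model) and applies
#' multiplicative lognormal replicate noise. With `cv = 0` the dataset
#' equals the model predictions exactly.
#'
#' @param design A [default_design()] object.
#' @param p A [td_params()] object.
#' @param d A [degradation_params()] object.
#' @param noise A [noise_spec()] object.
#' @return Data frame with columns `condition_id`, `c_dox0`, `c_dex0`,
#'   `time_h`, `replicate`, `viability`.
#' @examples
#' ds <- generate_viability(default_design(), td_params_ac16(),
#'                          default_degradation_params(), noise_spec(seed = 7))
#' nrow(ds)  # 240 records under the default design
#' @export
generate_viability <- function(design, p, d, noise = noise_spec()) {
  stopifnot(inherits(design, "design_spec"))
  cond <- design_conditions(design)
  m <- predict_viability_matrix(cond[, c("c_dox0", "c_dex0")], p, d,
                                design$timepoints)
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      time_i = seq_along(design$timepoints),
                      cond_i = seq_len(nrow(cond)))
  pred <- m[cbind(grid$time_i, grid$cond_i)]
  out <- data.frame(condition_id = cond$condition_id[grid$cond_i],
                    c_dox0 = cond$c_dox0[grid$cond_i],
                    c_dex0 = cond$c_dex0[grid$cond_i],
                    time_h = design$timepoints[grid$time_i],
                    replicate = grid$replicate,
                    viability = pred * noise_factors(nrow(grid), noise))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic degradation time course
#'
#' Mono-exponential decay of a drug in culture medium with
#' multiplicative lognormal noise.
#'
#' @param c0 Initial concentration (uM).
#' @param kdeg First-order degradation rate constant (1/h).
#' @param times Observation times (h).
#' @param noise A [noise_spec()] object.
#' @param drug Label for the output (`"DOX"` or `"DEX"`).
#' @return Data frame with columns `drug`, `time_h`, `conc_um`.
#' @export
generate_degradation <- function(c0, kdeg, times, noise = noise_spec(),
                                 drug = "DOX") {
  pred <- conc_at(c0, kdeg, times)
  data.frame(drug = drug, time_h = times,
             conc_um = pred * noise_factors(length(times), noise))
}

#' Generate synthetic clinical DEX concentration data
#'
#' Emulates phase-I style serum sampling after single 15-min DEX
#' infusions over a range of dose levels, using the two-compartment
#' model, with proportional noise. Peak concentrations scale linearly
#' with dose.
#'
#' @param doses_mg_per_m2 Dose levels (mg/m2), e.g. 50 to 2500.
#' @param p A [pk_params_dex()] object.
#' @param bsa Body surface area (m2).
#' @param times Sampling times after infusion start (h).
#' @param noise A [noise_spec()] object.
#' @param duration_h Infusion duration (h).
#' @return Data frame with columns `dose_mg_per_m2`, `bsa_m2`,
#'   `time_h`, `conc_mg_l`, `duration_h`.
#' @export
generate_dex_pk <- function(doses_mg_per_m2, p, bsa = 1.8,
                            times = c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24),
                            noise = noise_spec(), duration_h = 0.25) {
  stopifnot(all(doses_mg_per_m2 >= 0), all(times > 0))
  rows <- lapply(doses_mg_per_m2, function(dose) {
    reg <- build_regimen("DEX", dose, bsa = bsa, interval_h = 1,
                         n_doses = 1, duration_h = duration_h,
                         horizon_h = max(times))
    prof <- simulate_pk_dex(reg, p, grid = c(0, sort(unique(times))))
    data.frame(dose_mg_per_m2 = dose, bsa_m2 = bsa,
               time_h = times,
               conc_mg_l = prof$conc_mg_l[match(times, prof$time_h)],
               duration_h = duration_h)
  })
  out <- do.call(rbind, rows)
  out$conc_mg_l <- out$conc_mg_l * noise_factors(nrow(out), noise)
  rownames(out) <- NULL
  out
}
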