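# Pooled weighted least squares with a proportional residual-error model:
# all observations enter one objective with residuals (obs - pred)/pred.
# Positivity is enforced by optimizing log-transformed parameters, so
# log-scale standard errors are directly relative standard errors.

#' Options controlling the nonlinear least-squares fits
#'
#' @param n_starts Number of jittered candidate starts (in addition to
#'   the staged/default start) screened by objective value.
#' @param jitter_fold Multiplicative jitter half-range: candidate starts
#'   are drawn uniformly within `1/jitter_fold` .. `jitter_fold` of the
#'   base start, per parameter.
#' @param n_polish Number of top-ranked candidates refined with a full
#'   Levenberg-Marquardt run; the best final objective wins.
#' @param seed Seed for the jitter draws (fit results are deterministic
#'   given data and options).
#' @param maxiter Maximum Levenberg-Marquardt iterations per polish.
#' @param staged_init Build the base start by sequential prefits
#'   (control growth, then the DOX arm, then the DEX slope, then the
#'   interaction) before the joint fit?
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 10L, jitter_fold = 3, n_polish = 2L,
                        seed = 101L, maxiter = 200L, staged_init = TRUE) {
  stopifnot(n_starts >= 0, jitter_fold >= 1, n_polish >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 jitter_fold = jitter_fold,
                 n_polish = as.integer(n_polish), seed = as.integer(seed),
                 maxiter = as.integer(maxiter),
                 staged_init = isTRUE(staged_init)),
            class = "fit_options")
}

# Multi-start Levenberg-Marquardt on log-parameters. resid_fn maps a
# named log-parameter vector to the residual vector. Starts are ranked
# by initial sum of squares; only the best few are polished.
lm_multistart <- function(resid_fn, start_log, opts,
                          lower = rep(log(1e-8), length(start_log)),
                          upper = rep(log(1e8), length(start_log)),
                          extra_starts = list()) {
  starts <- c(list(start_log), extra_starts)
  if (opts$n_starts > 0) {
    jit <- with_seed(opts$seed, {
      matrix(runif(opts$n_starts * length(start_log),
                   -log(opts$jitter_fold), log(opts$jitter_fold)),
             nrow = opts$n_starts)
    })
    for (i in seq_len(opts$n_starts))
      starts[[i + 1]] <- pmin(pmax(start_log + jit[i, ], lower), upper)
  }
  sse <- vapply(starts, function(s) {
    r <- tryCatch(resid_fn(s), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) Inf else sum(r^2)
  }, numeric(1))
  ord <- order(sse)[seq_len(min(opts$n_polish, length(starts)))]
  fits <- lapply(ord, function(j) {
    tryCatch(
      minpack.lm::nls.lm(starts[[j]], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = opts$maxiter)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("all optimization starts failed", call. = FALSE)
  best <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  list(fit = best, start_sse = sse, n_polished = length(fits))
}

# Central-difference Jacobian of the residual vector w.r.t. log-params.
num_jacobian <- function(resid_fn, theta, h = 1e-6) {
  r0 <- resid_fn(theta)
  J <- matrix(NA_real_, length(r0), length(theta))
  for (j in seq_along(theta)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (resid_fn(tp) - resid_fn(tm)) / (2 * h)
  }
  colnames(J) <- names(theta)
  J
}

# Gauss-Newton covariance on the log scale; log-scale SE is the relative
# SE of the natural-scale estimate (delta method), so %RSE = 100 * SE_log.
gn_rse <- function(resid_fn, theta) {
  J <- num_jacobian(resid_fn, theta)
  r <- resid_fn(theta)
  dof <- max(length(r) - length(theta), 1)
  s2 <- sum(r^2) / dof
  JtJ <- crossprod(J)
  cov_log <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
  grad_norm <- sqrt(sum((crossprod(J, r))^2))
  if (is.null(cov_log) || any(!is.finite(diag(cov_log))) ||
      any(diag(cov_log) < 0))
    return(list(rse = setNames(rep(NA_real_, length(theta)), names(theta)),
                singular = TRUE, grad_norm = grad_norm))
  list(rse = 100 * sqrt(diag(cov_log)), singular = FALSE,
       grad_norm = grad_norm)
}

new_fit_result <- function(estimates, rse_percent, objective, convergence,
                           residuals, inestimable = character(0),
                           seed = NA_integer_) {
  structure(list(estimates = estimates, rse_percent = rse_percent,
                 objective = objective, convergence = convergence,
                 residuals = residuals, inestimable = inestimable,
                 seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model fit (", x$convergence$status, ", ",
      x$convergence$iterations, " iterations)\n", sep = "")
  tab <- data.frame(estimate = unlist(x$estimates),
                    rse_percent = x$rse_percent[names(x$estimates)])
  print(tab, digits = 4)
  if (length(x$inestimable))
    cat("inestimable (fixed at initial values):",
        paste(x$inestimable, collapse = ", "), "\n")
  cat("objective (weighted SSR):", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Fit a mono-exponential degradation curve
#'
#' Estimates the first-order degradation rate constant (and the initial
#' concentration) by ordinary least squares on log concentration, which
#' is the maximum-likelihood fit under multiplicative lognormal error.
#' Standard errors come from the linear-regression covariance.
#'
#' @param times Observation times (h), at least 3.
#' @param concs Concentrations (uM), strictly positive.
#' @return A `fit_result` with estimates `kdeg` (1/h) and `c0` (uM).
#' @examples
#' t <- c(0, 12, 24, 48, 72)
#' fit_exponential_decay(t, 1 * exp(-0.054 * t))
#' @export
fit_exponential_decay <- function(times, concs) {
  if (length(times) < 3 || length(times) != length(concs))
    stop("need >= 3 matched timepoints", call. = FALSE)
  if (any(concs <= 0))
    stop("concentrations must be strictly positive (log transform)",
         call. = FALSE)
  fit <- lm(log(concs) ~ times)
  kdeg <- -unname(coef(fit)[2])
  c0 <- exp(unname(coef(fit)[1]))
  se <- sqrt(diag(suppressWarnings(vcov(fit))))  # perfect fits warn
  est <- list(kdeg = kdeg, c0 = c0)
  rse <- c(kdeg = if (kdeg != 0) 100 * unname(se[2]) / abs(kdeg) else NA_real_,
           c0 = 100 * unname(se[1]))  # log-scale SE ~ relative SE
  new_fit_result(est, rse, objective = sum(stats::residuals(fit)^2),
                 convergence = list(status = "converged", iterations = 1L,
                                    grad_norm = 0),
                 residuals = data.frame(time_h = times,
                                        residual = stats::residuals(fit)))
}

validate_viability_data <- function(data) {
  need <- c("c_dox0", "c_dex0", "time_h", "replicate", "viability")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("viability data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(data$viability < 0))
    stop("viability must be >= 0", call. = FALSE)
  if (nrow(data) == 0) stop("empty viability dataset", call. = FALSE)
  split_cond <- unique(data[, c("c_dox0", "c_dex0")])
  no_t0 <- vapply(seq_len(nrow(split_cond)), function(i) {
    sel <- data$c_dox0 == split_cond$c_dox0[i] &
      data$c_dex0 == split_cond$c_dex0[i]
    !any(data$time_h[sel] == 0)
  }, logical(1))
  if (any(no_t0))
    stop("every condition needs a t = 0 record", call. = FALSE)
  invisible(data)
}

condition_class <- function(c_dox0, c_dex0) {
  ifelse(c_dox0 > 0 & c_dex0 > 0, "combo",
         ifelse(c_dox0 > 0, "dox",
                ifelse(c_dex0 > 0, "dex", "control")))
}

default_td_init <- function(data) {
  ctrl <- data$c_dox0 == 0 & data$c_dex0 == 0
  kg <- 0.01
  if (any(ctrl)) {
    cf <- coef(lm(log(pmax(data$viability[ctrl], 1e-6)) ~
                    data$time_h[ctrl]))
    kg <- max(unname(cf[2]), 1e-4)
  }
  dox_lv <- unique(data$c_dox0[data$c_dox0 > 0])
  dex_lv <- unique(data$c_dex0[data$c_dex0 > 0])
  c(kg = kg, r0 = 100, s_dox = 0.01, s_dex = 0.01, kmax_dox = 0.05,
    kc50_dox = if (length(dox_lv)) mean(range(dox_lv)) else 1,
    ktr_dox = 0.125, imax_dexi = 0.05,
    ic50_dexi = if (length(dex_lv)) mean(range(dex_lv)) else 50)
}

# Residual function over an arbitrary viability dataset: predictions from
# one stacked solve over the unique conditions and times.
make_td_resid <- function(data, d, base, free, clamp_net_kill = FALSE) {
  cond <- unique(data[, c("c_dox0", "c_dex0")])
  times <- sort(unique(data$time_h))
  ci <- match(paste(data$c_dox0, data$c_dex0),
              paste(cond$c_dox0, cond$c_dex0))
  ti <- match(data$time_h, times)
  obs <- data$viability
  function(log_free) {
    th <- base
    th[free] <- exp(log_free)
    m <- predict_viability_matrix(cond, th, d, times, clamp_net_kill)
    pred <- m[cbind(ti, ci)]
    (obs - pred) / pred
  }
}

#' Simultaneous fit of the cellular TD model
#'
#' Fits all nine TD parameters jointly to pooled control, single-agent
#' and combination viability data by weighted least squares with a
#' proportional residual-error model, on log-transformed parameters.
#' Degradation rate constants are fixed inputs (fitted separately with
#' [fit_exponential_decay()]). The base start is built by staged
#' prefits; a seeded multi-start jitter guards against local minima.
#' Parameters whose condition class is absent from the data (e.g. the
#' interaction `imax_dexi`/`ic50_dexi` without combination wells) are
#' flagged inestimable and held at their initial values. %RSE is
#' computed from the inverse Gauss-Newton Hessian approximation; if that
#' matrix is singular the fit is flagged non-identifiable instead of
#' reporting spurious precision.
#'
#' @param data Viability data frame with columns `c_dox0`, `c_dex0`
#'   (uM), `time_h`, `replicate`, `viability` (%).
#' @param d A [degradation_params()] object.
#' @param init Optional named starting values (full nine-parameter
#'   vector); defaults are derived from the data.
#' @param opts A [fit_options()] object.
#' @return A `fit_result`; `estimates` is a [td_params()] object.
#' @export
fit_td_simultaneous <- function(data, d, init = NULL,
                                opts = fit_options()) {
  validate_viability_data(data)
  cls <- condition_class(data$c_dox0, data$c_dex0)
  if (!any(cls == "control"))
    stop("identifiability: no control (untreated) condition in the data",
         call. = FALSE)
  has_dox <- any(cls %in% c("dox", "combo"))
  has_dex <- any(cls %in% c("dex", "combo"))
  has_combo <- any(cls == "combo")
  inest <- character(0)
  if (!has_dox) inest <- c(inest, "s_dox", "kmax_dox", "kc50_dox", "ktr_dox")
  if (!has_dex) inest <- c(inest, "s_dex")
  if (!has_combo) inest <- c(inest, "imax_dexi", "ic50_dexi")
  if (length(inest))
    message("absent condition classes leave parameters inestimable: ",
            paste(inest, collapse = ", "))
  free <- setdiff(.td_par_names, inest)

  base <- if (is.null(init)) default_td_init(data) else {
    stopifnot(all(.td_par_names %in% names(init)))
    init[.td_par_names]
  }

  # Staged prefits: each stage fits a small parameter block on the data
  # subset that informs it, holding everything else at the current base.
  stage <- function(pars, subset_cls) {
    sub <- data[cls %in% subset_cls, , drop = FALSE]
    pars <- intersect(pars, free)
    if (!nrow(sub) || !length(pars)) return(invisible(NULL))
    rf <- make_td_resid(sub, d, base, pars)
    f <- tryCatch(
      minpack.lm::nls.lm(log(base[pars]), fn = rf,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(f)) base[pars] <<- exp(coef(f))
    invisible(NULL)
  }
  if (opts$staged_init) {
    stage(c("kg", "r0"), "control")
    stage(c("s_dox", "kmax_dox", "kc50_dox", "ktr_dox"),
          c("control", "dox"))
    stage("s_dex", c("control", "dex"))
    stage(c("imax_dexi", "ic50_dexi"), "combo")
  }

  resid_fn <- make_td_resid(data, d, base, free)
  start_log <- log(base[free])
  ms <- lm_multistart(resid_fn, start_log, opts)
  fit <- ms$fit
  theta <- coef(fit)
  est <- base
  est[free] <- exp(theta)

  prec <- gn_rse(resid_fn, theta)
  rse <- setNames(rep(NA_real_, length(.td_par_names)), .td_par_names)
  rse[free] <- prec$rse[free]

  r <- resid_fn(theta)
  new_fit_result(
    estimates = structure(est, class = "td_params"),
    rse_percent = rse,
    objective = sum(r^2),
    convergence = list(
      status = if (prec$singular) "non-identifiable"
               else if (fit$info %in% 1:4) "converged" else "not-converged",
      iterations = fit$niter, message = fit$message,
      grad_norm = prec$grad_norm, n_polished = ms$n_polished,
      start_sse = ms$start_sse),
    residuals = data.frame(data[, c("c_dox0", "c_dex0", "time_h",
                                    "replicate")],
                           residual = r),
    inestimable = inest, seed = opts$seed)
}

validate_pk_data <- function(data) {
  need <- c("dose_mg_per_m2", "bsa_m2", "time_h", "conc_mg_l")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("PK data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(data$time_h <= 0))
    stop("PK observation times must be > 0 (post infusion start)",
         call. = FALSE)
  if (any(data$conc_mg_l <= 0))
    stop("concentrations must be > 0 for the proportional error model",
         call. = FALSE)
  invisible(data)
}

#' Fit the two-compartment DEX pharmacokinetic model
#'
#' Joint weighted least squares (proportional error) across all dose
#' levels, on log-transformed `kel`, `k12`, `k21` and `v`. Each dose is
#' modelled as a single constant-rate infusion starting at time 0.
#' Rate constants collapsing to the optimizer's lower bound (as happens
#' for `k12` when the data are truly one-compartmental) are flagged.
#'
#' @param data Data frame with columns `dose_mg_per_m2`, `bsa_m2`,
#'   `time_h` (> 0), `conc_mg_l` (> 0); optional `duration_h`
#'   (default 0.25).
#' @param init Optional named starting values (`kel`, `k12`, `k21`,
#'   `v`); defaults are derived from the data.
#' @param opts A [fit_options()] object (staging does not apply).
#' @return A `fit_result`; `estimates` is a [pk_params_dex()] object,
#'   with `boundary` listing any rate constants at the lower bound.
#' @export
fit_pk_dex <- function(data, init = NULL, opts = fit_options(n_starts = 5)) {
  validate_pk_data(data)
  if (length(unique(data$time_h)) < 2)
    stop("identifiability: need observations at >= 2 timepoints",
         call. = FALSE)
  if (!"duration_h" %in% names(data)) data$duration_h <- 0.25
  doses <- unique(data[, c("dose_mg_per_m2", "bsa_m2", "duration_h")])
  di <- match(paste(data$dose_mg_per_m2, data$bsa_m2),
              paste(doses$dose_mg_per_m2, doses$bsa_m2))
  pnames <- c("kel", "k12", "k21", "v")
  v0 <- max(doses$dose_mg_per_m2[1] * doses$bsa_m2[1] /
              max(data$conc_mg_l[di == 1]), 1)
  if (is.null(init)) init <- c(kel = 0.5, k12 = 0.5, k21 = 0.5, v = v0)
  stopifnot(all(pnames %in% names(init)))
  obs <- data$conc_mg_l
  resid_fn <- function(lth) {
    th <- exp(lth)
    p <- pk_params_dex(th[["kel"]], th[["k12"]], th[["k21"]], th[["v"]])
    pred <- numeric(length(obs))
    for (k in seq_len(nrow(doses))) {
      sel <- di == k
      tt <- sort(unique(data$time_h[sel]))
      reg <- build_regimen("DEX", doses$dose_mg_per_m2[k],
                           bsa = doses$bsa_m2[k], interval_h = 1,
                           n_doses = 1, duration_h = doses$duration_h[k],
                           horizon_h = max(tt))
      prof <- simulate_pk_dex(reg, p, grid = c(0, tt))
      pred[sel] <- prof$conc_mg_l[match(data$time_h[sel], prof$time_h)]
    }
    (obs - pred) / pred
  }
  lower <- rep(log(1e-8), 4)
  # a nested quasi-one-compartment candidate start (k12 ~ 0) keeps the
  # degenerate valley reachable when the data carry no distribution phase
  one_cpt <- log(c(kel = init[["kel"]], k12 = 1e-6, k21 = init[["kel"]],
                   v = v0))
  ms <- lm_multistart(resid_fn, log(init[pnames]), opts, lower = lower,
                      extra_starts = list(one_cpt))
  fit <- ms$fit
  theta <- coef(fit)
  est <- exp(theta)
  prec <- gn_rse(resid_fn, theta)
  boundary <- setdiff(pnames[theta <= lower + 0.5], "v")
  if (est[["k12"]] < 1e-4 * est[["kel"]])
    boundary <- unique(c(boundary, "k12"))
  if (length(boundary))
    message("rate constants collapsed toward zero ",
            "(a simpler model may suffice): ",
            paste(boundary, collapse = ", "))
  r <- resid_fn(theta)
  res <- new_fit_result(
    estimates = pk_params_dex(est[["kel"]], est[["k12"]], est[["k21"]],
                              est[["v"]]),
    rse_percent = setNames(prec$rse, pnames),
    objective = sum(r^2),
    convergence = list(
      status = if (prec$singular) "non-identifiable"
               else if (fit$info %in% 1:4) "converged" else "not-converged",
      iterations = fit$niter, message = fit$message,
      grad_norm = prec$grad_norm, n_polished = ms$n_polished),
    residuals = data.frame(data[, c("dose_mg_per_m2", "time_h")],
                           residual = r),
    seed = opts$seed)
  res$boundary <- boundary
  res
}

#' Serialize a fit result to JSON
#'
#' Writes estimates, precision, objective, convergence metadata and the
#' seed used for the multi-start draws.
#'
#' @param fit A `fit_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(estimates = as.list(unclass(fit$estimates)),
              rse_percent = as.list(fit$rse_percent),
              objective = fit$objective,
              convergence = fit$convergence[c("status", "iterations",
                                              "grad_norm")],
              inestimable = fit$inestimable,
              seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
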