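test_that("degradation closed form matches hand-computed values", {
  expect_identical(conc_at(1.0, 0.022, 0), 1.0)
  expect_identical(conc_at(10.0, 0.0, 100), 10.0)
  # 0.5 * exp(-0.022 * 24), evaluated independently
  expect_equal(conc_at(0.5, 0.022, 24), 0.294892, tolerance = 1e-5)
  expect_error(conc_at(-1, 0.022, 1), ">= 0")
})

test_that("degradation ODE co-integration agrees with the closed form", {
  rhs <- function(t, y, k) list(-k * y)
  tt <- seq(0, 72, by = 1)
  for (k in c(ref_deg$kdeg_dox, ref_deg$kdeg_dex)) {
    ode <- deSolve::lsoda(2.5, tt, rhs, k, rtol = 1e-10, atol = 1e-12)[, 2]
    expect_equal(ode, conc_at(2.5, k, tt), tolerance = 1e-8)
  }
})

test_that("the DOX kill Hill function has the right landmarks", {
  expect_identical(dox_kill_rate(0, ref_td), 0)
  expect_equal(dox_kill_rate(0.107, ref_td), 0.0697 / 2)
  expect_equal(dox_kill_rate(1e6, ref_td), 0.0697, tolerance = 1e-4)
  cc <- seq(0, 10, by = 0.5)
  expect_true(all(diff(dox_kill_rate(cc, ref_td)) > 0))
  expect_true(all(dox_kill_rate(cc, ref_td) < 0.0697))
})

test_that("the DEX inhibition Hill function has the right landmarks", {
  expect_identical(dex_inhibition_rate(0, ref_td), 0)
  expect_equal(dex_inhibition_rate(39, ref_td), 0.0625 / 2)
  expect_equal(dex_inhibition_rate(1e6, ref_td), 0.0625, tolerance = 1e-4)
})

test_that("control growth is exponential from the fitted baseline", {
  expect_equal(control_viability(0, ref_td), 101)
  p0 <- td_params(kg = 1e-12, r0 = 101, s_dox = 0.167, s_dex = 0.00968,
                  kmax_dox = 0.0697, kc50_dox = 0.107, ktr_dox = 0.126,
                  imax_dexi = 0.0625, ic50_dexi = 39)
  expect_equal(control_viability(50, p0), 101, tolerance = 1e-9)
  # 101 * exp(0.0115 * 72), evaluated independently
  expect_equal(control_viability(72, ref_td), 231.1517, tolerance = 1e-4)
})

test_that("td_rhs reproduces hand-evaluated derivatives", {
  st <- c(r = 101, k1 = 0, k2 = 0, k3 = 0)
  dr <- td_rhs(st, 0, 0, ref_td)
  expect_equal(dr[["r"]], 0.0115 * 101)
  expect_equal(unname(dr[c("k1", "k2", "k3")]), c(0, 0, 0))
  # net kill-chain input at KC50 / IC50: half-max kill minus half-max
  # inhibition = 0.0697/2 - 0.0625/2 = 0.0036
  dr2 <- td_rhs(st, 0.107, 39, ref_td)
  expect_equal(dr2[["k1"]] / ref_td[["ktr_dox"]], 0.0036)
})

test_that("td_rhs reduces to the single-agent equations", {
  set.seed(42)
  for (i in 1:1000) {
    st <- c(r = runif(1, 1, 200), k1 = runif(1, 0, 0.1),
            k2 = runif(1, 0, 0.1), k3 = runif(1, 0, 0.1))
    pp <- td_params(kg = runif(1, 0.001, 0.05), r0 = runif(1, 50, 150),
                    s_dox = runif(1, 0.01, 0.5), s_dex = runif(1, 0.001, 0.05),
                    kmax_dox = runif(1, 0.01, 0.2),
                    kc50_dox = runif(1, 0.05, 5), ktr_dox = runif(1, 0.05, 0.5),
                    imax_dexi = runif(1, 0.01, 0.2),
                    ic50_dexi = runif(1, 5, 100))
    cd <- runif(1, 0, 10)
    got <- td_rhs(st, cd, 0, pp)
    want <- oracle_dox_rhs(st[["r"]], st[["k1"]], st[["k2"]], st[["k3"]],
                           cd, pp[["kg"]], pp[["s_dox"]], pp[["kmax_dox"]],
                           pp[["kc50_dox"]], pp[["ktr_dox"]])
    expect_identical(unname(got), want)
    # DEX alone with empty kill chain: growth equation only
    st0 <- c(r = st[["r"]], k1 = 0, k2 = 0, k3 = 0)
    cx <- runif(1, 0, 100)
    expect_identical(td_rhs(st0, 0, cx, pp)[["r"]],
                     oracle_dex_rhs(st[["r"]], cx, pp[["kg"]], pp[["s_dex"]]))
  }
})

test_that("clamping floors the kill-chain input at zero", {
  st <- c(r = 100, k1 = 0, k2 = 0, k3 = 0)
  d_lit <- td_rhs(st, 0, 100, ref_td)
  d_cl <- td_rhs(st, 0, 100, ref_td, clamp_net_kill = TRUE)
  expect_true(d_lit[["k1"]] < 0)
  expect_identical(d_cl[["k1"]], 0)
})

test_that("the transit chain converges to its input, faster for larger ktr", {
  t95 <- function(ktr) {
    pp <- ref_td
    pp[["ktr_dox"]] <- ktr
    rhs <- function(t, y, parms)
      list(unname(td_rhs(setNames(y, c("r", "k1", "k2", "k3")),
                         c_dox = 5, c_dex = 0, pp)))
    tt <- seq(0, 400, by = 0.5)
    out <- deSolve::lsoda(c(100, 0, 0, 0), tt, rhs, NULL,
                          rtol = 1e-8, atol = 1e-10)
    target <- dox_kill_rate(5, pp)
    expect_equal(unname(out[nrow(out), 5]), target, tolerance = 1e-4)
    tt[which(out[, 5] >= 0.95 * target)[1]]
  }
  expect_lt(t95(0.252), t95(0.126))
})

test_that("in vitro simulation matches the control closed form", {
  s <- simulate_invitro(invitro_condition(0, 0), ref_td, ref_deg,
                        out_times = c(0, 12, 24, 48, 72))
  expect_equal(s$viability, control_viability(c(0, 12, 24, 48, 72), ref_td),
               tolerance = 1e-6)
  expect_equal(s$viability[4], 101 * exp(0.0115 * 48), tolerance = 1e-6)
})

test_that("DOX exposure kills and DEX co-treatment protects", {
  v_dox <- simulate_invitro(invitro_condition(0.5, 0), ref_td, ref_deg)
  v_ctrl <- control_viability(c(0, 12, 24, 48, 72), ref_td)
  expect_true(all(v_dox$viability[-1] < v_ctrl[-1]))
  # kill-chain input is pointwise lower at the higher DEX level
  tt <- seq(0, 72, by = 1)
  u <- function(cx0) {
    dox_kill_rate(conc_at(0.5, ref_deg$kdeg_dox, tt), ref_td) -
      dex_inhibition_rate(conc_at(cx0, ref_deg$kdeg_dex, tt), ref_td)
  }
  expect_true(all(u(100) < u(5)))
  v5 <- simulate_invitro(invitro_condition(0.5, 5), ref_td, ref_deg)
  v100 <- simulate_invitro(invitro_condition(0.5, 100), ref_td, ref_deg)
  expect_gt(v100$viability[5], v5$viability[5])
})

test_that("DOX PK obeys the dose/CL AUC identity and linearity", {
  reg <- build_regimen("DOX", 50, bsa = 1.8, interval_h = 504, n_doses = 1,
                       horizon_h = 20000)
  grid <- c(seq(0, 48, by = 0.05), seq(49, 20000, by = 1))
  prof <- simulate_pk_dox(reg, pk_params_dox_default(), grid)
  expect_equal(trap(prof$time_h, prof$conc_mg_l), 90 / 53.3,
               tolerance = 0.005)
  reg2 <- build_regimen("DOX", 100, bsa = 1.8, interval_h = 504,
                        n_doses = 1, horizon_h = 200)
  g2 <- seq(0, 200, by = 0.25)
  p1 <- simulate_pk_dox(build_regimen("DOX", 50, bsa = 1.8,
                                      interval_h = 504, n_doses = 1,
                                      horizon_h = 200),
                        pk_params_dox_default(), g2)
  p2 <- simulate_pk_dox(reg2, pk_params_dox_default(), g2)
  expect_equal(p2$conc_mg_l, 2 * p1$conc_mg_l, tolerance = 1e-8)
})

test_that("a zero-dose regimen yields an all-zero profile", {
  reg0 <- build_regimen("DOX", 0, bsa = 1.8, interval_h = 504, n_doses = 2)
  prof <- simulate_pk_dox(reg0, pk_params_dox_default(),
                          seq(0, 1008, by = 4))
  expect_true(all(prof$conc_mg_l == 0))
})

test_that("DEX PK obeys the dose/(kel*V) AUC identity", {
  reg <- build_regimen("DEX", 500, bsa = 1.8, interval_h = 504, n_doses = 1,
                       horizon_h = 150)
  grid <- seq(0, 150, by = 0.01)
  prof <- simulate_pk_dex(reg, pk_params_dex_default(), grid)
  expect_equal(trap(prof$time_h, prof$conc_mg_l), 900 / (1 * 14.6),
               tolerance = 0.005)
})

test_that("DEX PK degenerates to the 1-compartment closed form when k12 = 0", {
  p1c <- pk_params_dex(kel = 0.8, k12 = 1e-12, k21 = 1, v = 14.6)
  reg <- build_regimen("DEX", 500, bsa = 1.8, interval_h = 504, n_doses = 1,
                       horizon_h = 24)
  grid <- seq(0, 24, by = 0.25)
  prof <- simulate_pk_dex(reg, p1c, grid)
  rate <- 900 / 0.25
  closed <- ifelse(grid <= 0.25,
                   rate / (0.8 * 14.6) * (1 - exp(-0.8 * grid)),
                   rate / (0.8 * 14.6) * (1 - exp(-0.8 * 0.25)) *
                     exp(-0.8 * (grid - 0.25)))
  expect_equal(prof$conc_mg_l, closed, tolerance = 1e-6)
})

test_that("PK profile shifts with a shifted regimen, amounts stay nonnegative", {
  reg <- build_regimen("DEX", 500, bsa = 1.8, interval_h = 168, n_doses = 2)
  prof <- simulate_pk_dex(reg, pk_params_dex_default(),
                          seq(0, 336, by = 0.25))
  regs <- shift_regimen(reg, 24)
  profs <- simulate_pk_dex(regs, pk_params_dex_default(),
                           seq(0, 360, by = 0.25))
  expect_equal(profs$conc_mg_l[profs$time_h >= 24],
               prof$conc_mg_l, tolerance = 1e-7)
  expect_true(all(prof$conc_mg_l >= -1e-10))
})
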