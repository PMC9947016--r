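# Shared fixtures: reference parameter sets and an independent scalar
# implementation of the single-agent model equations, used as the oracle
# for reduction identities (kept deliberately separate from the package's
# vectorized right-hand side).

ref_td <- td_params_ac16()
ref_deg <- default_degradation_params()

# Single-agent DOX arm: growth with linear inhibition, Hill kill signal
# through three transit compartments.
oracle_dox_rhs <- function(r, k1, k2, k3, c_dox, kg, s_dox, kmax, kc50, ktr) {
  kdox <- kmax * c_dox / (kc50 + c_dox)
  dr <- (1 - s_dox * c_dox) * kg * r - k3 * r
  c(dr,
    ktr * (kdox - k1),
    ktr * (k1 - k2),
    ktr * (k2 - k3))
}

# Single-agent DEX arm: linear growth inhibition only.
oracle_dex_rhs <- function(r, c_dex, kg, s_dex) (1 - s_dex * c_dex) * kg * r

# Small trapezoid helper for profiles in tests.
trap <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# A short, cheap pair of regimens for translation tests (single cycle,
# 72-h horizon) so population / invariance checks stay fast.
cheap_regs <- function() {
  list(dox = build_regimen("DOX", 50, bsa = 1.8, interval_h = 72,
                           n_doses = 1),
       dex = build_regimen("DEX", 500, bsa = 1.8, interval_h = 72,
                           n_doses = 1))
}
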