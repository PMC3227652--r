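# Independent fixed-step integration oracle.
#
# The right-hand side is transcribed here reaction by reaction from the
# network scheme, deliberately sharing no code with the package
# implementation; classic fourth-order Runge-Kutta with a small fixed step
# then provides a solver-independent reference trajectory.

oracle_species <- c("R", "LR", "LRa", "LRaI", "Sc", "pSc", "Cc", "Dc", "Hc",
                    "mc", "I", "Sn", "pSn", "Cn", "Dn", "Hn", "mn")

oracle_rhs <- function(y, k, L) {
  v1 <- k[2] * L * y[1]                       # L + R -> LR
  v2 <- k[1] * y[2]                           # LR -> L + R
  v3 <- k[3] * y[2]                           # LR -> LRa
  v4 <- k[4] * y[3]                           # LRa -> LR
  v5 <- k[5] * y[3] * y[11]                   # LRa + I -> LRaI
  v6 <- k[6] * y[4]                           # LRaI -> LRa + I
  v7 <- k[7] * y[3] * y[5]                    # Sc -> pSc (by LRa)
  imp_S <- k[8] * y[5];  exp_S <- k[9] * y[12]
  imp_pS <- k[8] * y[6]; exp_pS <- k[9] * y[13]
  imp_C <- k[8] * y[7];  exp_C <- k[9] * y[14]
  don_c <- k[10] * y[6] * y[6]; doff_c <- k[11] * y[8]
  hon_c <- k[10] * y[6] * y[7]; hoff_c <- k[11] * y[9]
  don_n <- k[10] * y[13] * y[13]; doff_n <- k[11] * y[15]
  hon_n <- k[10] * y[13] * y[14]; hoff_n <- k[11] * y[16]
  imp_D <- k[12] * y[8]; imp_H <- k[12] * y[9]
  v13 <- k[13] * y[13]                        # pSn -> Sn
  hh <- y[16]^k[20]
  v14 <- k[14] * hh / (k[15]^k[20] + hh)      # -> mn (by Hn)
  v16 <- k[16] * y[17]                        # mn -> mc
  v17 <- k[17] * y[10]                        # mc ->
  v18 <- k[18] * y[10]                        # -> I (by mc)
  v19 <- k[19] * y[11]                        # I ->
  c(v2 - v1,                                           # R
    v1 - v2 - v3 + v4,                                 # LR
    v3 - v4 - v5 + v6,                                 # LRa
    v5 - v6,                                           # LRaI
    exp_S - imp_S - v7,                                # Sc
    v7 + exp_pS - imp_pS - 2 * don_c + 2 * doff_c - hon_c + hoff_c,  # pSc
    exp_C - imp_C - hon_c + hoff_c,                    # Cc
    don_c - doff_c - imp_D,                            # Dc
    hon_c - hoff_c - imp_H,                            # Hc
    v16 - v17,                                         # mc
    v18 + v6 - v5 - v19,                               # I
    imp_S - exp_S + v13,                               # Sn
    imp_pS - exp_pS - v13 - 2 * don_n + 2 * doff_n - hon_n + hoff_n, # pSn
    imp_C - exp_C - hon_n + hoff_n,                    # Cn
    don_n - doff_n + imp_D,                            # Dn
    hon_n - hoff_n + imp_H,                            # Hn
    v14 - v16)                                         # mn
}

# RK4 over [0, t_end] with fixed step; returns states at `times` (each a
# multiple of dt). L_pM is a scalar (pM) or a function of time returning pM.
oracle_rk4 <- function(y0, k, L_pM, t_end, dt = 0.05,
                       times = seq(0, t_end, by = 60)) {
  Lfun <- if (is.function(L_pM)) function(t) L_pM(t) / 1000
    else function(t) L_pM / 1000
  y <- unname(y0)
  k <- unname(k)
  out <- matrix(NA_real_, nrow = length(times), ncol = 17,
                dimnames = list(NULL, oracle_species))
  ti <- 1L
  nstep <- round(t_end / dt)
  if (times[1] == 0) { out[1, ] <- y; ti <- 2L }
  for (i in seq_len(nstep)) {
    t <- (i - 1) * dt
    h1 <- oracle_rhs(y, k, Lfun(t))
    h2 <- oracle_rhs(y + dt / 2 * h1, k, Lfun(t + dt / 2))
    h3 <- oracle_rhs(y + dt / 2 * h2, k, Lfun(t + dt / 2))
    h4 <- oracle_rhs(y + dt * h3, k, Lfun(t + dt))
    y <- y + dt / 6 * (h1 + 2 * h2 + 2 * h3 + h4)
    while (ti <= length(times) && times[ti] <= i * dt + 1e-9) {
      out[ti, ] <- y
      ti <- ti + 1L
    }
  }
  list(times = times, states = out)
}

# two-phase oracle simulation; returns the nuclear heterodimer output (pM)
oracle_simulate <- function(params, totals = tgfscreen::total_concentrations(),
                            L_pM = 200, t_end = 3600, dt = 0.05,
                            times = seq(0, t_end, by = 60)) {
  k <- unname(unclass(tgfscreen::as_parameter_set(params)))
  y0 <- numeric(17)
  y0[1] <- totals[["R_tot"]]
  y0[5] <- totals[["S_tot"]]
  y0[7] <- totals[["C_tot"]]
  eq <- oracle_rk4(y0, k, 1e-6, t_end = 3600, dt = dt, times = 3600)
  ph2 <- oracle_rk4(eq$states[1, ], k, L_pM, t_end = t_end, dt = dt,
                    times = times)
  tibble::tibble(time_s = ph2$times, output_pM = ph2$states[, "Hn"] * 1000)
}
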