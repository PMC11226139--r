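# Independent oracles used by the test suite. These re-derive results along
# routes that do not share code with the package internals: a pure-R
# transcription of the TP06 right-hand side integrated with deSolve::lsoda, a
# high-order numeric quadrature of the Q1 element matrices, a fine parametric
# quadrature of the truncated-ellipsoid volume, and plain brute-force
# aggregations.

.cache_env <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.cache_env[[name]])) .cache_env[[name]] <- force(expr)
  .cache_env[[name]]
}

# ---- pure-R TP06 right-hand side (epicardial base, ICaL mixture) ----------
tp06_rhs_r <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    RT <- 8314.472 * 310 / 96485.3415
    Ek <- RT * log(5.4 / Ki); Ena <- RT * log(140 / Nai)
    Eks <- RT * log((5.4 + 0.03 * 140) / (Ki + 0.03 * Nai))
    Eca <- 0.5 * RT * log(2 / Cai)
    INa <- 14.838 * m^3 * h * j * (V - Ena)
    z <- 2 * (V - 15) / RT; ez <- exp(z)
    drive <- 3.98e-5 * 4 * (V - 15) * 96485.3415 / RT *
      (0.25 * CaSS * ez - 2) / (ez - 1)
    ICaLwt <- drive * d_wt * f_wt * f2 * fCass
    ICaLts <- drive * d_ts * f_ts * f2 * fCass
    ICaL <- (1 - rho) * ICaLwt + rho * ICaLts
    Ito <- 0.294 * r * s * (V - Ek)
    IKr <- 0.153 * Xr1 * Xr2 * (V - Ek)
    IKs <- 0.392 * iksf * Xs^2 * (V - Eks)
    Ak1 <- 0.1 / (1 + exp(0.06 * (V - Ek - 200)))
    Bk1 <- (3 * exp(2e-4 * (V - Ek + 100)) + exp(0.1 * (V - Ek - 10))) /
      (1 + exp(-0.5 * (V - Ek)))
    IK1 <- 5.405 * Ak1 / (Ak1 + Bk1) * (V - Ek)
    INaCa <- 1000 * (exp(0.35 * V / RT) * Nai^3 * 2 -
                       exp(-0.65 * V / RT) * 140^3 * Cai * 2.5) /
      ((87.5^3 + 140^3) * (1.38 + 2) * (1 + 0.1 * exp(-0.65 * V / RT)))
    INaK <- 2.724 * (5.4 / 6.4) * (Nai / (Nai + 40)) /
      (1 + 0.1245 * exp(-0.1 * V / RT) + 0.0353 * exp(-V / RT))
    IpCa <- 0.1238 * Cai / (5e-4 + Cai)
    IpK <- 0.0146 * (V - Ek) / (1 + exp((25 - V) / 5.98))
    IbNa <- 2.9e-4 * (V - Ena); IbCa <- 5.92e-4 * (V - Eca)
    istim <- parms[["amp"]]  # caller integrates stimulus-on/off piecewise
    Iion <- INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa + IpK +
      IbNa + IbCa

    minf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
    taum <- (1 / (1 + exp((-60 - V) / 5))) *
      (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
    hinf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
    if (V >= -40) {
      ah <- 0; bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
      aj <- 0; bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
    } else {
      ah <- 0.057 * exp(-(V + 80) / 6.8)
      bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
      aj <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
        (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
      bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
    }
    xr1inf <- 1 / (1 + exp((-26 - V) / 7))
    tauxr1 <- 450 / (1 + exp((-45 - V) / 10)) * 6 / (1 + exp((V + 30) / 11.5))
    xr2inf <- 1 / (1 + exp((V + 88) / 24))
    tauxr2 <- 3 / (1 + exp((-60 - V) / 20)) * 1.12 / (1 + exp((V - 60) / 20))
    xsinf <- 1 / (1 + exp((-5 - V) / 14))
    tauxs <- 1400 / sqrt(1 + exp((5 - V) / 6)) / (1 + exp((V - 35) / 15)) + 80
    rinf <- 1 / (1 + exp((20 - V) / 6))
    taur <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
    sinf <- 1 / (1 + exp((V + 20) / 5))
    taus <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
    dinf_wt <- 1 / (1 + exp((va_wt - V) / 7.5))
    dinf_ts <- 1 / (1 + exp((va_ts - V) / 7.5))
    taud <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
      (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
    finf_wt <- 1 / (1 + exp((V - vina_wt) / 7))
    finf_ts <- 1 / (1 + exp((V - vina_ts) / 12))
    tauf <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
      180 / (1 + exp((V + 30) / 10)) + 20
    f2inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
    tauf2 <- 562 * exp(-(V + 27)^2 / 240) + 31 / (1 + exp((25 - V) / 10)) +
      80 / (1 + exp((V + 30) / 10))
    fcassinf <- 0.6 / (1 + (CaSS / 0.05)^2) + 0.4
    taufcass <- 80 / (1 + (CaSS / 0.05)^2) + 2

    kCaSR <- 2.5 - 1.5 / (1 + (1.5 / CaSR)^2)
    k1 <- 0.15 / kCaSR; k2 <- 0.045 * kCaSR
    dRbar <- 0.005 * (1 - Rbar) - k2 * CaSS * Rbar
    O <- k1 * CaSS^2 * Rbar / (0.06 + k1 * CaSS^2)
    Irel <- 0.102 * O * (CaSR - CaSS)
    Ileak <- 3.6e-4 * (CaSR - Cai)
    Iup <- 0.006375 / (1 + 2.5e-4^2 / Cai^2)
    Ixfer <- 0.0038 * (CaSS - Cai)
    Vc <- 0.016404; Vsr <- 0.001094; Vss <- 5.468e-5; Cap <- 0.185
    F <- 96485.3415
    bsr <- 1 / (1 + 10 * 0.3 / (CaSR + 0.3)^2)
    bss <- 1 / (1 + 0.4 * 2.5e-4 / (CaSS + 2.5e-4)^2)
    bc <- 1 / (1 + 0.2 * 0.001 / (Cai + 0.001)^2)
    list(c(
      V = -Iion + istim,
      Ki = -(IK1 + Ito + IKr + IKs - 2 * INaK + IpK - istim) / (Vc * F) * Cap,
      Nai = -(INa + IbNa + 3 * INaK + 3 * INaCa) / (Vc * F) * Cap,
      Cai = bc * (-(IbCa + IpCa - 2 * INaCa) / (2 * Vc * F) * Cap -
                    (Iup - Ileak) * (Vsr / Vc) + Ixfer),
      CaSS = bss * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                      ICaL / (2 * Vss * F) * Cap),
      CaSR = bsr * (Iup - Irel - Ileak),
      m = (minf - m) / taum, h = (hinf - h) / (1 / (ah + bh)),
      j = (hinf - j) / (1 / (aj + bj)),
      Xr1 = (xr1inf - Xr1) / tauxr1, Xr2 = (xr2inf - Xr2) / tauxr2,
      Xs = (xsinf - Xs) / tauxs, r = (rinf - r) / taur,
      s = (sinf - s) / taus,
      d_wt = (dinf_wt - d_wt) / taud, f_wt = (finf_wt - f_wt) / tauf,
      d_ts = (dinf_ts - d_ts) / taud, f_ts = (finf_ts - f_ts) / tauf,
      f2 = (f2inf - f2) / tauf2, fCass = (fcassinf - fCass) / taufcass,
      Rbar = dRbar))
  })
}

# one paced beat: stimulus on for [0, stim_dur), then free; piecewise
# integration avoids the forcing discontinuity
lsoda_tp06_beat <- function(y0, t_end, dt = 1, rho = 0, iksf = 1, amp = 52,
                            stim_dur = 1, va_wt = -8, vina_wt = -20,
                            va_ts = -8, vina_ts = 0) {
  skip_if_not_installed("deSolve")
  base <- c(rho = rho, iksf = iksf, va_wt = va_wt, vina_wt = vina_wt,
            va_ts = va_ts, vina_ts = vina_ts)
  t1 <- seq(0, stim_dur, by = min(dt, 0.25))
  sol1 <- deSolve::lsoda(y0, t1, tp06_rhs_r, c(base, amp = amp),
                         rtol = 1e-8, atol = 1e-8)
  y1 <- sol1[nrow(sol1), -1]
  t2 <- seq(stim_dur, t_end, by = dt)
  sol2 <- deSolve::lsoda(y1, t2, tp06_rhs_r, c(base, amp = 0),
                         rtol = 1e-8, atol = 1e-8)
  sol2
}

# ---- Q1 element matrices on the unit cube by fine Gauss quadrature --------
q1_unit_cube_matrices <- function(ngauss = 4) {
  gl <- statmod_gauss(ngauss)
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  signs <- signs[c(1, 2, 4, 3, 5, 6, 8, 7), ]  # VTK ordering
  K <- matrix(0, 8, 8); M <- matrix(0, 8, 8)
  for (a in seq_len(ngauss)) for (b in seq_len(ngauss)) for (cc in seq_len(ngauss)) {
    xi <- gl$nodes[a]; eta <- gl$nodes[b]; ze <- gl$nodes[cc]
    w <- gl$weights[a] * gl$weights[b] * gl$weights[cc]
    N <- (1 + signs[, 1] * xi) * (1 + signs[, 2] * eta) *
      (1 + signs[, 3] * ze) / 8
    dN <- cbind(signs[, 1] * (1 + signs[, 2] * eta) * (1 + signs[, 3] * ze),
                (1 + signs[, 1] * xi) * signs[, 2] * (1 + signs[, 3] * ze),
                (1 + signs[, 1] * xi) * (1 + signs[, 2] * eta) * signs[, 3]) / 8
    # unit cube: x = (xi+1)/2 so J = I/2, detJ = 1/8, grad = 2*dN
    K <- K + w * (2 * dN) %*% t(2 * dN) * (1 / 8)
    M <- M + w * tcrossprod(N) * (1 / 8)
  }
  list(K = K, M = M)
}

# Gauss-Legendre nodes/weights on [-1,1] (Golub-Welsch, no dependencies)
statmod_gauss <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b; A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}

# ---- truncated-ellipsoid volume by fine parametric quadrature -------------
ellipsoid_volume_quadrature <- function(spec, n = 80) {
  gl <- statmod_gauss(24)
  map01 <- function(range) list(x = (gl$nodes + 1) / 2 * diff(range) + range[1],
                                w = gl$weights / 2 * diff(range))
  qp <- map01(spec$phi_range); qt <- map01(spec$theta_range); qr <- map01(c(0, 1))
  total <- 0
  for (it in seq_along(qt$x)) for (ir in seq_along(qr$x)) {
    th <- qt$x[it]; r <- qr$x[ir]
    a <- spec$a1 + r * (spec$a2 - spec$a1)
    b <- spec$b1 + r * (spec$b2 - spec$b1)
    cc <- spec$c1 + r * (spec$c2 - spec$c1)
    da <- spec$a2 - spec$a1; db <- spec$b2 - spec$b1; dc <- spec$c2 - spec$c1
    # |det d(x,y,z)/d(phi,theta,r)| integrated analytically in phi
    ph <- qp$x; wph <- qp$w
    tphi <- cbind(-a * cos(th) * sin(ph), b * cos(th) * cos(ph), 0)
    ttheta <- cbind(-a * sin(th) * cos(ph), -b * sin(th) * sin(ph),
                    cc * cos(th))
    tr <- cbind(da * cos(th) * cos(ph), db * cos(th) * sin(ph), dc * sin(th))
    dets <- tphi[, 1] * (ttheta[, 2] * tr[, 3] - ttheta[, 3] * tr[, 2]) -
      tphi[, 2] * (ttheta[, 1] * tr[, 3] - ttheta[, 3] * tr[, 1]) +
      tphi[, 3] * (ttheta[, 1] * tr[, 2] - ttheta[, 2] * tr[, 1])
    total <- total + sum(abs(dets) * wph) * qt$w[it] * qr$w[ir]
  }
  total
}

# ---- brute-force dispersion over a marker table ----------------------------
dispersion_brute_force <- function(markers) {
  rng <- function(x) max(x) - min(x)
  needles <- unique(markers$needle)
  rt <- ad <- numeric(length(needles))
  for (k in seq_along(needles)) {
    sub <- markers[markers$needle == needles[k], ]
    rt[k] <- rng(sub$repo); ad[k] <- rng(sub$apd)
  }
  list(dAT_tot = rng(markers$acti), dRT_tot = rng(markers$repo),
       dRT_trans = mean(rt), dRT_trans_sd = stats::sd(rt),
       dAPD_tot = rng(markers$apd), dAPD_trans = mean(ad),
       dAPD_trans_sd = stats::sd(ad))
}

# shared fixtures -------------------------------------------------------------
table1_report_cached <- function() {
  cached("table1", run_table1("cable1d", n_beats = 8))
}

transmural_iks <- function(het, n = 61) {
  lay <- c(rep("ENDO", floor(n / 3)), rep("MID", n - 2 * floor(n / 3)),
           rep("EPI", floor(n / 3)))
  vapply(lay, iks_factor_for, numeric(1), het_setting = het)
}
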