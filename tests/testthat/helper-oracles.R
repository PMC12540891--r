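# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the cubic fugacity oracle integrates the defining
# volume integral numerically, and the PC-SAFT oracle is a separate
# term-by-term re-implementation of the residual Helmholtz energy.

R_GAS <- 8.314462618
KB <- 1.380649e-23

# --- cubic EoS: pressure as a function of (T, V, n) -------------------------

cubic_pressure_tvn <- function(eos, T, V, n, a, b, kij, lij) {
  nc <- length(n)
  N <- sum(n)
  K <- (1 - diag(nc)) * kij
  L <- (1 - diag(nc)) * lij
  aij <- sqrt(outer(a, a)) * (1 - K)
  bij <- outer(b, b, function(x, z) (x + z) / 2) * (1 - L)
  Am <- drop(n %*% aij %*% n)            # N^2 a_m
  Bm <- drop(n %*% bij %*% n) / N        # N b_m
  d <- if (eos == "pr") c(1 + sqrt(2), 1 - sqrt(2)) else c(1, 0)
  N * R_GAS * T / (V - Bm) - Am / ((V + d[1] * Bm) * (V + d[2] * Bm))
}

# ln phi_i by adaptive quadrature of the residual volume integral
# RT ln phi_i = int_V^inf [ (dP/dn_i)_{T,V} - RT/V ] dV - RT ln Z,
# with dP/dn_i by central differences and the substitution u = 1/V.
cubic_lnphi_quadrature <- function(eos, T, P, y, a, b, kij, lij) {
  mix <- cubic_mix_params(y, list(
    structure(list(a = a[1], b = b[1], eos = eos), class = "cubic_pure_params"),
    structure(list(a = a[2], b = b[2], eos = eos), class = "cubic_pure_params")),
    kij, lij)
  A <- mix$a_m * P / (R_GAS * T)^2
  B <- mix$b_m * P / (R_GAS * T)
  Z <- cubic_solve_z(eos, A, B)$Z
  V0 <- Z * R_GAS * T / P               # molar volume == total V for 1 mol
  vapply(seq_along(y), function(i) {
    # dP/dn_i differentiated by hand from the explicit P(T, V, n) above:
    # with A = sum_jk n_j n_k a_jk, B = (sum_jk n_j n_k b_jk) / N,
    # A_i = 2 sum_j n_j a_ij, B_i = (2 sum_j n_j b_ij - B) / N
    nc <- length(y)
    K <- (1 - diag(nc)) * kij
    L <- (1 - diag(nc)) * lij
    aij <- sqrt(outer(a, a)) * (1 - K)
    bij <- outer(b, b, function(x, z) (x + z) / 2) * (1 - L)
    d <- if (eos == "pr") c(1 + sqrt(2), 1 - sqrt(2)) else c(1, 0)
    N <- sum(y)
    Am <- drop(y %*% aij %*% y)
    Bm <- drop(y %*% bij %*% y) / N
    Ai <- 2 * drop(aij %*% y)[i]
    Bi <- (2 * drop(bij %*% y)[i] - Bm) / N
    dPdn <- function(V) {
      D <- (V + d[1] * Bm) * (V + d[2] * Bm)
      R_GAS * T / (V - Bm) + N * R_GAS * T * Bi / (V - Bm)^2 - Ai / D +
        Am * Bi * (d[1] * (V + d[2] * Bm) + d[2] * (V + d[1] * Bm)) / D^2
    }
    integrand <- function(u) (dPdn(1 / u) - R_GAS * T * u) / u^2
    val <- NULL
    for (rt in c(1e-12, 1e-11, 1e-10)) {
      val <- tryCatch(stats::integrate(Vectorize(integrand), 0, 1 / V0,
                                       rel.tol = rt, subdivisions = 800L)$value,
                      error = function(e) NULL)
      if (!is.null(val)) break
    }
    if (is.null(val)) stop("quadrature failed to converge")
    val / (R_GAS * T) - log(Z)
  }, numeric(1))
}

# --- PC-SAFT: independent term-by-term re-implementation --------------------

# Universal dispersion constants retyped from the published tables
# (independent transcription from the package's copy).
PC_ORACLE_A <- matrix(c(
  0.9105631445, -0.3084016918, -0.0906148351,
  0.6361281449, 0.1860531159, 0.4527842806,
  2.6861347891, -2.5030047259, 0.5962700728,
  -26.547362491, 21.419793629, -1.7241829131,
  97.759208784, -65.255885330, -4.1302112531,
  -159.59154087, 83.318680481, 13.776631870,
  91.297774084, -33.746922930, -8.6728470368), ncol = 3, byrow = TRUE)
PC_ORACLE_B <- matrix(c(
  0.7240946941, -0.5755498075, 0.0976883116,
  2.2382791861, 0.6995095521, -0.2557574982,
  -4.0025849485, 3.8925673390, -9.1558561530,
  -21.003576815, -17.215471648, 20.642075974,
  26.855641363, 192.67226447, -38.804430052,
  206.55133841, -161.82646165, 93.626774077,
  -355.60235612, -165.20769346, -29.666905585), ncol = 3, byrow = TRUE)

# reduced residual Helmholtz energy at (T, eta, x); scalar loops throughout
pcsaft_ares_oracle <- function(T, eta, x, m, sigma, eps, kij_mat) {
  n <- length(x)
  d <- numeric(n)
  for (i in 1:n) d[i] <- sigma[i] * (1 - 0.12 * exp(-3 * eps[i] / T))
  sum_md3 <- 0
  for (i in 1:n) sum_md3 <- sum_md3 + x[i] * m[i] * d[i]^3
  rho <- 6 / pi * eta / sum_md3
  z <- numeric(4)
  for (k in 0:3) for (i in 1:n) z[k + 1] <- z[k + 1] + pi / 6 * rho * x[i] * m[i] * d[i]^k
  mbar <- sum(x * m)
  om <- 1 - z[4]
  a_hs <- (3 * z[2] * z[3] / om + z[3]^3 / (z[4] * om^2) +
             (z[3]^3 / z[4]^2 - z[1]) * log(om)) / z[1]
  a_chain <- 0
  for (i in 1:n) {
    gii <- 1 / om + (d[i] / 2) * 3 * z[3] / om^2 + (d[i] / 2)^2 * 2 * z[3]^2 / om^3
    a_chain <- a_chain - x[i] * (m[i] - 1) * log(gii)
  }
  m2es3 <- 0; m2e2s3 <- 0
  for (i in 1:n) for (j in 1:n) {
    sij <- (sigma[i] + sigma[j]) / 2
    eij <- sqrt(eps[i] * eps[j]) * (1 - kij_mat[i, j])
    m2es3 <- m2es3 + x[i] * x[j] * m[i] * m[j] * (eij / T) * sij^3
    m2e2s3 <- m2e2s3 + x[i] * x[j] * m[i] * m[j] * (eij / T)^2 * sij^3
  }
  I1 <- 0; I2 <- 0
  for (k in 0:6) {
    ak <- PC_ORACLE_A[k + 1, 1] + (mbar - 1) / mbar * PC_ORACLE_A[k + 1, 2] +
      (mbar - 1) * (mbar - 2) / mbar^2 * PC_ORACLE_A[k + 1, 3]
    bk <- PC_ORACLE_B[k + 1, 1] + (mbar - 1) / mbar * PC_ORACLE_B[k + 1, 2] +
      (mbar - 1) * (mbar - 2) / mbar^2 * PC_ORACLE_B[k + 1, 3]
    I1 <- I1 + ak * eta^k
    I2 <- I2 + bk * eta^k
  }
  C1 <- 1 / (1 + mbar * (8 * eta - 2 * eta^2) / om^4 +
               (1 - mbar) * (20 * eta - 27 * eta^2 + 12 * eta^3 - 2 * eta^4) /
               ((1 - eta) * (2 - eta))^2)
  a_disp <- -2 * pi * rho * I1 * m2es3 - pi * rho * mbar * C1 * I2 * m2e2s3
  mbar * a_hs + a_chain + a_disp
}

# Richardson-extrapolated central difference
central_diff <- function(f, x, h = 1e-6) {
  d1 <- (f(x + h) - f(x - h)) / (2 * h)
  d2 <- (f(x + h / 2) - f(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

# --- shared fixtures --------------------------------------------------------

tiny_dataset <- function() {
  grid <- expand.grid(T_K = c(310, 320), P_MPa = c(10, 15, 20, 25))
  grid$rho_kg_m3 <- 900 - 6 * (grid$T_K - 310) + 8 * (grid$P_MPa - 10)
  p <- density_model_params("chrastil", -20, 2, -1000)
  grid$y <- predict_density_model(p, grid$T_K, grid$P_MPa, grid$rho_kg_m3)
  grid$sd_y <- 0.01 * grid$y
  grid$sol_g_L <- NA_real_
  solubility_dataset(grid, "toy", 295.4, 44.01)
}
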