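co2p <- co2_properties()
sump <- sumatriptan_properties()

test_that("pure parameters follow the PR and SRK defining expressions", {
  R <- 8.314462618
  # PR for CO2 at its critical temperature: alpha = 1
  p <- cubic_pure_params("pr", 304.1, 7.38e6, 0.225, 304.1)
  expect_equal(p$a, 0.45724 * R^2 * 304.1^2 / 7.38e6, tolerance = 1e-12)
  expect_equal(p$a, 0.3961, tolerance = 1e-3)
  expect_equal(p$b, 2.666e-5, tolerance = 1e-3)
  # alpha-function slopes
  expect_equal(cubic_pure_params("pr", 1160.3, 3.39e6, 0.647, 308)$alpha_slope,
               1.2594, tolerance = 1e-4)
  expect_equal(cubic_pure_params("srk", 304.1, 7.38e6, 0.225, 308)$alpha_slope,
               0.8252, tolerance = 1e-4)
})

test_that("vdW2 mixing rules reduce correctly and match the hand expansion", {
  pr <- function(a, b) structure(list(a = a, b = b, eos = "pr"),
                                 class = "cubic_pure_params")
  # single component: interaction terms vanish
  m1 <- cubic_mix_params(1, list(pr(0.4, 3e-5)), k_ij = 0.3, l_ij = -0.5)
  expect_equal(m1$a_m, 0.4); expect_equal(m1$b_m, 3e-5)
  # identical species with zero interaction: mixture equals the pure
  m2 <- cubic_mix_params(c(0.3, 0.7), list(pr(0.4, 3e-5), pr(0.4, 3e-5)))
  expect_equal(m2$a_m, 0.4); expect_equal(m2$b_m, 3e-5)
  # hand expansion of the double sum: 0.25*1 + 2*0.25*2 + 0.25*4 = 2.25
  m3 <- cubic_mix_params(c(0.5, 0.5), list(pr(1, 1e-5), pr(4, 2e-5)))
  expect_equal(m3$a_m, 2.25)
  expect_error(cubic_mix_params(c(0.5, 0.6), list(pr(1, 1e-5), pr(4, 2e-5))),
               "sum to 1")
})

test_that("the compressibility root satisfies the cubic and its limits", {
  expect_equal(cubic_solve_z("pr", 0, 0)$Z, 1)
  expect_equal(cubic_solve_z("srk", 0, 0)$Z, 1)
  # residual check over a sweep of (A, B)
  for (eos in c("pr", "srk")) for (A in c(0.05, 0.3, 1)) for (B in c(0.01, 0.05, 0.1)) {
    z <- cubic_solve_z(eos, A, B)$Z
    resid <- if (eos == "pr")
      z^3 - (1 - B) * z^2 + (A - 3 * B^2 - 2 * B) * z - (A * B - B^2 - B^3)
    else z^3 - z^2 + (A - B - B^2) * z - A * B
    expect_lt(abs(resid), 1e-12)
    expect_gt(z, B)
  }
  expect_error(cubic_solve_z("pr", 0.4, -0.1))
})

test_that("molar volume from Z matches a dense bracketing root scan in v", {
  # pure CO2 at 308.2 K / 30 MPa: solve the pressure-explicit PR form in v
  # with an independent brute-force bracket + uniroot scan
  T <- 308.2; P <- 30e6
  pu <- cubic_pure_params("pr", co2p$Tc, co2p$Pc, co2p$omega, T)
  A <- pu$a * P / (R_GAS * T)^2; B <- pu$b * P / (R_GAS * T)
  v_pkg <- cubic_solve_z("pr", A, B)$Z * R_GAS * T / P
  pfun <- function(v) R_GAS * T / (v - pu$b) -
    pu$a / (v * (v + pu$b) + pu$b * (v - pu$b)) - P
  vg <- exp(seq(log(pu$b * 1.0001), log(1), length.out = 4000))
  roots <- c()
  for (i in seq_len(length(vg) - 1))
    if (is.finite(pfun(vg[i])) && is.finite(pfun(vg[i + 1])) &&
        pfun(vg[i]) * pfun(vg[i + 1]) < 0)
      roots <- c(roots, uniroot(pfun, vg[i:(i + 1)], tol = 1e-18)$root)
  expect_equal(length(roots), 1L)   # supercritical: single volume root
  expect_equal(v_pkg, roots[1], tolerance = 1e-9)
})

test_that("analytic ln phi matches quadrature of the volume integral", {
  set.seed(11)
  for (rep in 1:8) {
    eos <- sample(c("pr", "srk"), 1)
    T <- runif(1, 308, 340); P <- runif(1, 8e6, 32e6)
    y2 <- 10^runif(1, -6, -2); y <- c(1 - y2, y2)
    kij <- runif(1, -0.3, 0.3); lij <- runif(1, -0.6, 0.6)
    pures <- list(cubic_pure_params(eos, co2p$Tc, co2p$Pc, co2p$omega, T),
                  cubic_pure_params(eos, sump$Tc, sump$Pc, sump$omega, T))
    a <- vapply(pures, `[[`, 0, "a"); b <- vapply(pures, `[[`, 0, "b")
    lp <- cubic_fugacity(eos, T, P, y, pures, kij, lij)$ln_phi
    lq <- cubic_lnphi_quadrature(eos, T, P, y, a, b, kij, lij)
    expect_equal(lp, lq, tolerance = 1e-8)
  }
})

test_that("fugacity coefficients obey limiting laws", {
  T <- 320
  pures <- list(cubic_pure_params("pr", co2p$Tc, co2p$Pc, co2p$omega, T),
                cubic_pure_params("pr", sump$Tc, sump$Pc, sump$omega, T))
  # ideal-gas limit P -> 0: phi -> 1 and Z -> 1
  fg <- cubic_fugacity("pr", T, 1, c(0.999, 0.001), pures, -0.1, -0.4)
  expect_equal(fg$phi, c(1, 1), tolerance = 1e-5)
  expect_equal(fg$Z, 1, tolerance = 1e-6)
  # infinite dilution: solvent phi equals pure-solvent phi
  fg2 <- cubic_fugacity("pr", T, 15e6, c(1 - 1e-12, 1e-12), pures, -0.1, -0.4)
  fgp <- cubic_fugacity("pr", T, 15e6, 1, pures[1])
  expect_equal(fg2$ln_phi[1], fgp$ln_phi[1], tolerance = 1e-9)
})

test_that("Gibbs-Duhem holds along composition at fixed T and P", {
  T <- 318.2; P <- 20e6
  pures <- list(cubic_pure_params("pr", co2p$Tc, co2p$Pc, co2p$omega, T),
                cubic_pure_params("pr", sump$Tc, sump$Pc, sump$omega, T))
  set.seed(3)
  for (rep in 1:6) {
    y2 <- runif(1, 1e-4, 0.02)
    h <- 1e-7
    lp <- function(z2) cubic_fugacity("pr", T, P, c(1 - z2, z2), pures,
                                      -0.1, -0.45)$ln_phi
    dln <- (lp(y2 + h) - lp(y2 - h)) / (2 * h)
    expect_lt(abs(sum(c(1 - y2, y2) * dln)), 1e-8 * max(1, abs(dln[2])))
  }
})

test_that("solid solubility solves the equilibrium relation to tolerance", {
  T <- 308.2; P <- 30e6
  y2 <- cubic_solid_solubility("pr", T, P, sump, co2p, -0.1, -0.5)
  # residual of the defining fixed point
  pures <- list(cubic_pure_params("pr", co2p$Tc, co2p$Pc, co2p$omega, T),
                cubic_pure_params("pr", sump$Tc, sump$Pc, sump$omega, T))
  Ps <- sublimation_pressure(sump, T)
  phi2 <- cubic_fugacity("pr", T, P, c(1 - y2, y2), pures, -0.1, -0.5)$phi[2]
  rhs <- Ps / P / phi2 * exp(sump$v_solid * (P - Ps) / (8.314462618 * T))
  expect_equal(y2, rhs, tolerance = 1e-9)
  expect_error(cubic_solid_solubility("pr", 300, P, sump, co2p), "supercritical")
})

test_that("solubility increases with sublimation pressure at fixed state", {
  T <- 318.2; P <- 20e6
  scale <- c(0.5, 1, 2, 4)
  ys <- vapply(scale, function(s) {
    an <- sumatriptan_properties()$pvap_anchors
    an$P_Pa <- an$P_Pa * s
    sp <- solute_properties("x", 295.4, 830.5, 1160.3, 3.39e6, 0.647, 3.052e-4, an)
    cubic_solid_solubility("pr", T, P, sp, co2p, -0.1, -0.5)
  }, numeric(1))
  expect_true(all(diff(ys) > 0))
})

test_that("isotherm regression recovers known interaction parameters", {
  grid <- default_grid()
  grid <- grid[abs(grid$T_K - 318.2) < 0.01, ]
  spec <- synthetic_spec(list(type = "cubic", eos = "pr", solute = sump,
                              solvent = co2p, k_ij = -0.1, l_ij = -0.4),
                         grid = grid, noise_rsd = 0)
  d <- generate_synthetic(spec)
  fit <- fit_cubic_isotherm("pr", d, sump, co2p)
  expect_equal(fit$k_ij, -0.1, tolerance = 1e-3)
  expect_equal(fit$l_ij, -0.4, tolerance = 1e-3)
  expect_lt(fit$stats$aard_pct, 0.05)
})
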