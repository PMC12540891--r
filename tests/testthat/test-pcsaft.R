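co2pc <- co2_pcsaft()
drugpc <- sumatriptan_pcsaft_synthetic()

test_that("residual Helmholtz energy matches the independent re-implementation", {
  set.seed(21)
  for (rep in 1:12) {
    T <- runif(1, 300, 360); eta <- runif(1, 0.05, 0.55)
    y2 <- runif(1, 1e-6, 0.4); x <- c(1 - y2, y2)
    kij <- runif(1, -0.3, 0.3)
    st <- pcsaft_state(T, eta, x, list(co2pc, drugpc), kij)
    a_or <- pcsaft_ares_oracle(T, eta, x,
                               c(co2pc$m, drugpc$m),
                               c(co2pc$sigma, drugpc$sigma),
                               c(co2pc$eps_k, drugpc$eps_k),
                               matrix(c(0, kij, kij, 0), 2))
    expect_equal(st$a_res, a_or, tolerance = 1e-12)
  }
})

test_that("ideal-gas limits: a_res -> 0, Z -> 1, phi -> 1 as eta -> 0", {
  st <- pcsaft_state(320, 1e-9, c(0.999, 0.001), list(co2pc, drugpc), -0.1)
  expect_equal(st$a_res, 0, tolerance = 1e-7)
  expect_equal(st$Z, 1, tolerance = 1e-7)
  expect_equal(st$ln_phi, c(0, 0), tolerance = 1e-6)
})

test_that("chain term vanishes for m = 1: a_hc reduces to hard sphere", {
  ones <- list(pcsaft_pure(1, 3.2, 200), pcsaft_pure(1, 3.8, 260))
  st <- pcsaft_state(320, 0.3, c(0.6, 0.4), ones, 0)
  # independent Boublik-Mansoori evaluation
  x <- c(0.6, 0.4); sg <- c(3.2, 3.8); ep <- c(200, 260)
  d <- sg * (1 - 0.12 * exp(-3 * ep / 320))
  rho <- 6 / pi * 0.3 / sum(x * d^3)
  z <- vapply(0:3, function(k) pi / 6 * rho * sum(x * d^k), 0)
  om <- 1 - z[4]
  ahs <- (3 * z[2] * z[3] / om + z[3]^3 / (z[4] * om^2) +
            (z[3]^3 / z[4]^2 - z[1]) * log(om)) / z[1]
  expect_equal(st$a_hc, ahs, tolerance = 1e-12)
})

test_that("analytic Z matches Richardson finite differences of a_res in eta", {
  set.seed(5)
  for (rep in 1:10) {
    T <- runif(1, 305, 345); eta <- runif(1, 0.05, 0.5)
    y2 <- 10^runif(1, -6, -1); x <- c(1 - y2, y2)
    st <- pcsaft_state(T, eta, x, list(co2pc, drugpc), -0.12)
    dade <- central_diff(function(e)
      pcsaft_ares(T, e, x, list(co2pc, drugpc), -0.12), eta)
    expect_equal(st$Z, 1 + eta * dade, tolerance = 1e-7)
  }
})

test_that("analytic ln phi matches mole-number finite differences at fixed T,V", {
  set.seed(9)
  for (rep in 1:6) {
    T <- runif(1, 305, 345); eta <- runif(1, 0.1, 0.45)
    y2 <- runif(1, 1e-4, 0.2); x <- c(1 - y2, y2)
    st <- pcsaft_state(T, eta, x, list(co2pc, drugpc), -0.1)
    if (st$Z <= 0) next   # unstable branch: fugacity undefined
    rho <- st$rho
    # F(n) = N * a_res(T, N/V, n/N) at fixed V; ln phi_k = dF/dn_k + (Z-1) d?/..
    V <- 1e5
    Ntot <- rho * V
    n0 <- x * Ntot
    dF <- vapply(1:2, function(k) {
      g <- function(nk) {
        nv <- n0; nv[k] <- nk; N <- sum(nv)
        dd <- c(co2pc$sigma, drugpc$sigma) *
          (1 - 0.12 * exp(-3 * c(co2pc$eps_k, drugpc$eps_k) / T))
        mm <- c(co2pc$m, drugpc$m)
        eta_n <- pi / 6 * (N / V) * sum((nv / N) * mm * dd^3)
        N * pcsaft_ares(T, eta_n, nv / N, list(co2pc, drugpc), -0.1)
      }
      central_diff(g, n0[k], h = n0[k] * 1e-2)
    }, numeric(1))
    expect_equal(st$ln_phi, dF - log(st$Z), tolerance = 1e-6)
  }
})

test_that("Gibbs-Duhem holds for PC-SAFT fugacities at fixed T and P", {
  T <- 318.2; P <- 20e6
  set.seed(13)
  for (rep in 1:5) {
    y2 <- runif(1, 1e-4, 0.05)
    h <- 1e-7
    lp <- function(z2) pcsaft_fugacity(T, P, c(1 - z2, z2),
                                       list(co2pc, drugpc), -0.1,
                                       phase_hint = "liquid")$ln_phi
    dln <- (lp(y2 + h) - lp(y2 - h)) / (2 * h)
    expect_lt(abs(sum(c(1 - y2, y2) * dln)), 1e-7 * max(1, abs(dln[2])))
  }
})

test_that("a binary of identical components reproduces the pure fluid", {
  twin <- list(pcsaft_pure(2.0729, 2.7852, 169.21),
               pcsaft_pure(2.0729, 2.7852, 169.21))
  for (split in c(0.2, 0.5, 0.9)) {
    stb <- pcsaft_state(310, 0.25, c(split, 1 - split), twin, 0)
    stp <- pcsaft_state(310, 0.25, 1, list(co2pc), 0)
    expect_equal(stb$a_res, stp$a_res, tolerance = 1e-12)
    expect_equal(stb$Z, stp$Z, tolerance = 1e-12)
    expect_equal(stb$ln_phi, rep(stp$ln_phi, 2), tolerance = 1e-10)
  }
})

test_that("density solver round-trips pressure and obeys the ideal limit", {
  st <- pcsaft_density(308.2, 30e6, 1, list(co2pc), 0, "liquid")
  expect_lt(abs(st$P - 30e6) / 30e6, 1e-10)
  # CO2 mass density within 5% of the tabulated experimental value
  rho_mass <- st$rho * 1e30 / 6.02214076e23 * 44.01 / 1000
  expect_equal(rho_mass, 929.85, tolerance = 0.05)
  # near-ideal state: number density approaches P/kT
  stl <- pcsaft_density(400, 100, 1, list(co2pc), 0, "vapor")
  expect_equal(stl$rho * 1e30, 100 / (1.380649e-23 * 400), tolerance = 1e-3)
})

test_that("PC-SAFT solubility satisfies its fixed-point relation", {
  sump <- sumatriptan_properties()
  y2 <- pcsaft_solid_solubility(308.2, 30e6, drugpc, co2pc, sump, -0.05)
  Ps <- sublimation_pressure(sump, 308.2)
  fg <- pcsaft_fugacity(308.2, 30e6, c(1 - y2, y2), list(co2pc, drugpc), -0.05,
                        phase_hint = "liquid")
  rhs <- Ps / 30e6 / fg$phi[2] *
    exp(sump$v_solid * (30e6 - Ps) / (8.314462618 * 308.2))
  expect_equal(y2, rhs, tolerance = 1e-9)
})

test_that("k_ij regression recovers the truth and is seed-stable", {
  sump <- sumatriptan_properties()
  grid <- default_grid()
  grid <- grid[abs(grid$T_K - 308.2) < 0.01, ]
  spec <- synthetic_spec(list(type = "pcsaft", solute_pc = drugpc,
                              solvent_pc = co2pc, solute = sump, k_ij = -0.15),
                         grid = grid, noise_rsd = 0)
  d <- generate_synthetic(spec)
  f1 <- fit_pcsaft_isotherm(d, drugpc, co2pc, sump, seed = 1)
  expect_equal(f1$k_ij, -0.15, tolerance = 1e-3)
  expect_lt(f1$stats$aard_pct, 0.05)
  f2 <- fit_pcsaft_isotherm(d, drugpc, co2pc, sump, seed = 202)
  expect_equal(f1$k_ij, f2$k_ij, tolerance = 1e-6)
})
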