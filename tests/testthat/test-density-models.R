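test_that("model predictions match direct evaluation of the closed forms", {
  p <- density_model_params("chrastil", -20, 2, -1000)
  expect_equal(predict_density_model(p, 308, 10, 800),
               exp(-20 + 2 * log(800) - 1000 / 308), tolerance = 1e-12)
  expect_equal(predict_density_model(p, 308, 10, 800), 5.13e-5, tolerance = 1e-3)

  # degenerate K-J: constant in rho and T
  pk <- density_model_params("kj", -5, 0, 0)
  expect_equal(predict_density_model(pk, 310, 10, 400),
               predict_density_model(pk, 340, 30, 900))
  expect_equal(predict_density_model(pk, 310, 10, 400), exp(-5))

  # all-zero MST at 1 bar gives y = 1
  pm <- density_model_params("mst", 0, 0, 0)
  expect_equal(predict_density_model(pm, 310, 0.1, 500), 1)

  # Bartle at reference state: y = exp(a0 + a1/T) at P = P_ref, rho = rho_ref
  pb <- density_model_params("bartle", 3, -5000, 0.01)
  expect_equal(predict_density_model(pb, 320, 0.1, 700), exp(3 - 5000 / 320))

  expect_error(predict_density_model(p, -1, 10, 800), "domain error")
})

test_that("Chrastil and K-J predictions increase with density when a1 > 0", {
  rhos <- seq(300, 950, length.out = 40)
  for (id in c("chrastil", "kj")) {
    a1 <- if (id == "chrastil") 3 else 0.005
    p <- density_model_params(id, -22, a1, -4500)
    y <- predict_density_model(p, 318, 15, rhos)
    expect_true(all(diff(y) > 0), label = id)
  }
})

test_that("each model recovers its own coefficients from noiseless data", {
  grid <- default_grid()
  truth <- list(
    chrastil = density_model_params("chrastil", -26, 4.5, -4900),
    kj = density_model_params("kj", -1.0, 0.0063, -4750),
    bartle = density_model_params("bartle", 16, -7150, 0.0098),
    mst = density_model_params("mst", -9800, 3.3, 17.0))
  for (id in names(truth)) {
    spec <- synthetic_spec(list(type = "density", params = truth[[id]]),
                           grid = grid, noise_rsd = 0)
    d <- generate_synthetic(spec)
    fit <- fit_density_model(id, d)
    for (cf in c("a0", "a1", "a2"))
      expect_equal(fit$params[[cf]], truth[[id]][[cf]], tolerance = 5e-4,
                   label = paste(id, cf))
    expect_lt(fit$stats$aard_pct, 0.1)
  }
})

test_that("fitting is invariant to row order and bitwise repeatable", {
  d <- load_dataset("sumatriptan")
  f1 <- fit_density_model("kj", d)
  shuffled <- solubility_dataset(as.data.frame(d)[rev(seq_len(nrow(d))), ],
                                 "sumatriptan", 295.40, 44.01)
  f2 <- fit_density_model("kj", shuffled)
  expect_equal(unlist(f1$params[c("a0", "a1", "a2")]),
               unlist(f2$params[c("a0", "a1", "a2")]), tolerance = 1e-6)
  f3 <- fit_density_model("kj", d)
  expect_identical(f1$params$a2, f3$params$a2)
})

test_that("sse_log objective reproduces the linearized least-squares optimum", {
  d <- load_dataset("sumatriptan")
  f <- fit_density_model("chrastil", d, objective = "sse_log")
  cf <- coef(lm(log(y) ~ log(rho_kg_m3) + I(1 / T_K), data = as.data.frame(d)))
  expect_equal(unname(unlist(f$params[c("a0", "a1", "a2")])), unname(cf),
               tolerance = 1e-9)
})

test_that("enthalpy derivation applies dH = -R a and the exact identity", {
  d <- load_dataset("sumatriptan")
  fc <- fit_density_model("chrastil", d)
  fb <- fit_density_model("bartle", d)
  # frozen coefficient examples: -R a / 1000 in kJ/mol
  fb_known <- fb; fb_known$params$a1 <- -7196.1
  fc_known <- fc; fc_known$params$a2 <- -4927.6
  e <- derive_enthalpies(fc_known, fb_known)
  expect_equal(e$dH_vap, 8.314462618 * 7196.1 / 1000, tolerance = 1e-12)
  expect_equal(e$dH_vap, 59.83, tolerance = 1e-3)
  expect_equal(e$dH_total, 40.97, tolerance = 1e-3)
  expect_equal(e$dH_sol, e$dH_total - e$dH_vap)

  # zero coefficients give zero enthalpies
  fc_known$params$a2 <- 0; fb_known$params$a1 <- 0
  e0 <- derive_enthalpies(fc_known, fb_known)
  expect_equal(unlist(unclass(e0)), c(dH_total = 0, dH_vap = 0, dH_sol = 0))

  expect_error(derive_enthalpies(fb, fc), "chrastil")
})

test_that("MST transform collapses self-consistent data onto a line", {
  grid <- default_grid()
  p <- density_model_params("mst", -9800, 3.3, 17.0)
  d <- generate_synthetic(synthetic_spec(list(type = "density", params = p),
                                         grid = grid, noise_rsd = 0))
  fit <- fit_density_model("mst", d)
  pts <- mst_consistency_points(d, fit)
  expect_equal(attr(pts, "r2_line"), 1, tolerance = 1e-9)
  # the line is value = a0 + a1 rho
  expect_equal(pts$value, p$a0 + p$a1 * pts$rho, tolerance = 1e-5)

  one <- solubility_dataset(as.data.frame(d)[1, ], "x", 295.4, 44.01)
  expect_error(mst_consistency_points(one, fit), ">= 2")
})

test_that("fixture data are MST-consistent (near-linear transform)", {
  d <- load_dataset("sumatriptan")
  fit <- fit_density_model("mst", d)
  pts <- mst_consistency_points(d, fit)
  expect_gte(attr(pts, "r2_line"), 0.95)
})

test_that("crossover detection reports the grid interval of the sign flip", {
  d <- load_dataset("sumatriptan")
  cx <- find_crossover(d)
  expect_equal(cx$interval, c(15, 18))
  # below the crossover y decreases with T, above it increases
  y12 <- d[d$P_MPa == 12, ]; y12 <- y12[order(y12$T_K), "y"]
  y30 <- d[d$P_MPa == 30, ]; y30 <- y30[order(y30$T_K), "y"]
  expect_true(all(diff(y12) < 0))
  expect_true(all(diff(y30) > 0))

  one <- solubility_dataset(as.data.frame(d)[d$T_K == 308.2, ], "x", 295.4, 44.01)
  expect_error(find_crossover(one), ">= 2 isotherms")

  # monotone dataset: no sign change, empty interval with diagnostic
  p <- density_model_params("kj", -1.0, 0.0063, -2000)  # density effect dominates everywhere
  mono <- generate_synthetic(synthetic_spec(list(type = "density", params = p),
                                            noise_rsd = 0))
  cx2 <- find_crossover(mono)
  expect_length(cx2$interval, 0)
  expect_match(cx2$diagnostic, "no negative-to-positive")
})
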