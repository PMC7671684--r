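test_that("L from Po_max follows the saturation formula with boundary guards", {
  expect_equal(estimate_L(0.5)$L, 1)             # the reduced-Po_max design
  # frozen from exact arithmetic: 0.94/0.06 = 47/3 = 15.6667
  expect_equal(estimate_L(0.94)$L, 47 / 3, tolerance = 1e-12)
  expect_equal(estimate_L(0.94)$L, 15.667, tolerance = 1e-4)
  expect_error(estimate_L(1.0), "unidentifiable")
  expect_error(estimate_L(0), "positive")
  # delta-method SE
  expect_equal(estimate_L(0.5, se = 0.02)$se, 0.02 / 0.25)
})

test_that("K_D from EC50 and L with delta-method error propagation", {
  expect_equal(estimate_KD(0.7, 0)$K_D, 0.7)     # no gating amplification
  # frozen: 0.14 * (1 + 47/3) = 7/3 = 2.3333
  expect_equal(estimate_KD(0.14, 47 / 3)$K_D, 7 / 3, tolerance = 1e-12)
  expect_equal(estimate_KD(0.22, 1)$K_D, 0.44)   # reduced-Po_max capsaicin
  expect_error(estimate_KD(-1, 2), "positive")
  kd <- estimate_KD(2, 3, ec50_se = 0.1, L_se = 0.5)
  expect_equal(kd$se, sqrt(16 * 0.01 + 4 * 0.25))
})

test_that("predict_po saturates at L/(1+L) and halves at K_D/(1+L)", {
  m <- channel_model(K_D = 5, L = 4)
  expect_equal(predict_po(m, 1e9), 4 / 5, tolerance = 1e-6)
  expect_equal(predict_po(m, 5 / 5), (4 / 5) / 2, tolerance = 1e-12)
  expect_equal(predict_po(m, 5), 4 / 6, tolerance = 1e-12)  # c = K_D
  expect_error(predict_po(m, -1), "negative")
})

test_that("predict_po is monotone in c and L and decreasing in K_D", {
  set.seed(14)
  for (i in 1:100) {
    KD <- stats::runif(1, 0.05, 50)
    L <- stats::runif(1, 0.1, 40)
    m <- channel_model(K_D = KD, L = L)
    cc <- sort(stats::runif(20, 0, 100))
    po <- predict_po(m, cc)
    expect_true(all(diff(po) >= -1e-14))
    # numerically verified half-maximum location
    ec50 <- KD / (1 + L)
    expect_equal(predict_po(m, ec50), L / (1 + L) / 2, tolerance = 1e-12)
    expect_gt(predict_po(channel_model(K_D = KD, L = L * 1.5), 1),
              predict_po(m, 1) - 1e-14)
    expect_lt(predict_po(channel_model(K_D = KD * 1.5, L = L), 1),
              predict_po(m, 1) + 1e-14)
  }
})

test_that("two-step estimators invert the generating model exactly", {
  m <- channel_model(K_D = 3.7, L = 6.2)
  po_max <- predict_po(m, 1e12)
  L <- estimate_L(po_max)$L
  cc <- exp(seq(log(0.001), log(1000), length.out = 30))
  ec50 <- fit_hill(dose_response_curve(cc, predict_po(m, cc)))$ec50
  KD <- estimate_KD(ec50, L)$K_D
  expect_equal(L, 6.2, tolerance = 1e-6)
  expect_equal(KD, 3.7, tolerance = 1e-5)
})

test_that("direct three-state fit recovers noiseless parameters", {
  m <- channel_model(K_D = 0.44, L = 1)  # reduced-Po_max scenario
  cc <- exp(seq(log(0.005), log(50), length.out = 15))
  fit <- fit_three_state(dose_response_curve(cc, predict_po(m, cc)))
  expect_equal(fit$K_D, 0.44, tolerance = 1e-6)
  expect_equal(fit$L, 1, tolerance = 1e-6)
})

test_that("high-Po_max curves trigger the identifiability ridge warning", {
  m <- channel_model(K_D = 10, L = 100)   # Po_max ~ 0.99
  cc <- exp(seq(log(0.001), log(100), length.out = 20))
  expect_warning(fit_three_state(dose_response_curve(cc, predict_po(m, cc))),
                 "ridge")
  expect_error(fit_three_state(dose_response_curve(cc, rep(0.9, 20))),
               "identifiability")
})

test_that("three-state parameter recovery at 5% noise is within 15% median error", {
  m <- channel_model(K_D = 0.44, L = 1)
  cc <- exp(seq(log(0.01), log(20), length.out = 8))
  errs <- vapply(1:100, function(s) {
    crv <- simulate_dose_response(m, cc, noise_sd = 0.05, seed = s)
    crv$response <- pmin(pmax(crv$response, 1e-4), 0.999)
    f <- tryCatch(suppressWarnings(fit_three_state(crv)),
                  error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    abs(f$K_D - 0.44) / 0.44
  }, numeric(1))
  expect_lt(stats::median(errs, na.rm = TRUE), 0.15)
})

test_that("Eyring energies follow the equilibrium constants", {
  # L = 1: open and liganded-closed states are isoenergetic
  p <- eyring_profile(list(L = 1, K_D = 2), c = 5)
  expect_equal(p$G[p$state == "OL"], p$G[p$state == "CL"])
  # c = K_D: binding energy is zero
  p2 <- eyring_profile(list(L = 4, K_D = 5), c = 5)
  expect_equal(p2$G[p2$state == "CL"], 0, tolerance = 1e-12)
  # frozen from -RT log(c/K_D) and -RT log(L) at RT = 1.98720425e-3*295.15:
  # G(CL) = -0.85356, G(OL) = -2.46740 kcal/mol
  p3 <- eyring_profile(list(L = 47 / 3, K_D = 7 / 3), c = 10, T = 295.15)
  expect_equal(p3$G[p3$state == "CL"], -0.85356, tolerance = 1e-4)
  expect_equal(p3$G[p3$state == "OL"], -2.46740, tolerance = 1e-4)
  expect_error(eyring_profile(list(L = 2, K_D = 1), c = 0), "diverges")
})

test_that("Eyring energy differences are reference-invariant and unit-consistent", {
  est <- list(L = 12, K_D = 1.8)
  a <- eyring_profile(est, c = 10)
  b <- eyring_profile(est, c = 3)
  # G(OL) - G(CL) = -RT ln L does not depend on concentration
  expect_equal(diff(a$G[2:3]), diff(b$G[2:3]), tolerance = 1e-12)
  kt <- eyring_profile(est, c = 10, units = "kT")
  RT <- 1.98720425e-3 * 295.15
  expect_equal(kt$G, a$G / RT, tolerance = 1e-12)
  # unbinding barrier from the rate equation is positive for ms-scale rates
  wb <- eyring_profile(est, c = 10, off_rate = 1 / 50)
  expect_gt(attr(wb, "barrier"), 10)
})

test_that("delta-method SEs agree with a parametric bootstrap within 20%", {
  # reduced-Po_max scenario fitted over many noise realizations; the
  # bootstrap SD of the two-step (L, K_D) estimates is compared with the
  # delta-method SEs propagated from a single fit's asymptotic errors
  m <- channel_model(K_D = 0.44, L = 1)
  cc <- exp(seq(log(0.005), log(50), length.out = 12))
  po0 <- predict_po(m, cc)
  sd_noise <- 0.02
  fit_once <- function(seed) {
    set.seed(seed)
    crv <- dose_response_curve(cc, po0 + stats::rnorm(length(cc), 0, sd_noise))
    f <- suppressWarnings(fit_hill(crv))  # low points may dip below zero
    L <- estimate_L(f$max, f$max_se)
    KD <- estimate_KD(f$ec50, L$L, f$ec50_se, L$se)
    c(L = L$L, L_se = L$se, KD = KD$K_D, KD_se = KD$se)
  }
  boot <- t(vapply(1:200, fit_once, numeric(4)))
  # median delta-method SE across fits vs the empirical SD of estimates
  expect_lt(abs(stats::median(boot[, "L_se"]) - stats::sd(boot[, "L"])) /
              stats::sd(boot[, "L"]), 0.20)
  expect_lt(abs(stats::median(boot[, "KD_se"]) - stats::sd(boot[, "KD"])) /
              stats::sd(boot[, "KD"]), 0.20)
})
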