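echem_4pl <- function() four_pl(a = -15.2, b = -0.64, c = 8.92, d = -12.5)
elisa_4pl <- function() four_pl(a = 0.183, b = 1.83, c = 79.4, d = 3.63)

test_that("4PL response at the inflection point is the asymptote midpoint", {
  for (p in list(echem_4pl(), elisa_4pl()))
    expect_equal(predict_4pl(p, p$c), (p$a + p$d) / 2, tolerance = 1e-12)
})

test_that("noise-free 4PL refits recover both printed parameter sets to 0.1%", {
  x <- 10^seq(0, 3, length.out = 8)
  for (truth in list(echem_4pl(), elisa_4pl())) {
    fit <- fit_4pl(calibration_data(x, predict_4pl(truth, x)))
    for (nm in c("a", "b", "c", "d"))
      expect_lt(abs(fit[[nm]] / truth[[nm]] - 1), 1e-3)
    expect_gt(fit$r2, 0.9999)
  }
})

test_that("degenerate calibration inputs are rejected", {
  x <- 10^seq(0, 3, length.out = 8)
  expect_error(fit_4pl(calibration_data(x, rep(1, 8))), "flat|unidentifiable")
  expect_error(fit_4pl(calibration_data(c(1, 10, 100),
                                        c(0.1, 0.5, 0.9))), ">= 4")
  expect_error(calibration_data(c(-1, 1, 10, 100), 1:4), "> 0")
})

test_that("4PL inversion is the exact inverse on the open response range", {
  p <- echem_4pl()
  expect_equal(invert_4pl(p, (p$a + p$d) / 2), p$c, tolerance = 1e-12)
  expect_equal(invert_4pl(p, predict_4pl(p, 100)), 100, tolerance = 1e-9)
  expect_error(invert_4pl(p, p$a), "range")
  expect_error(invert_4pl(p, -100), "range")
  ## randomized parameters vs a bisection oracle
  set.seed(7)
  for (k in 1:20) {
    q <- four_pl(a = runif(1, -20, -10), b = runif(1, -2, -0.3),
                 c = runif(1, 1, 50), d = runif(1, -10, -1))
    y <- runif(1, min(q$a, q$d) + 0.1, max(q$a, q$d) - 0.1)
    bis <- uniroot(function(x) predict_4pl(q, x) - y,
                   interval = c(1e-9, 1e9), tol = 1e-13)$root
    expect_equal(invert_4pl(q, y), bis, tolerance = 1e-6)
  }
})

test_that("LOD converts 3.3 sigma through the local 4PL slope", {
  p <- echem_4pl()
  set.seed(21)
  conc <- c(1, 3, 10, 30, 100, 300)
  sigma <- 0.05
  ## replicates: noiseless at the reference, known-sigma elsewhere
  resp <- unlist(lapply(conc, function(x) {
    mu <- predict_4pl(p, x)
    if (x == 1) rep(mu, 5) + rnorm(5, 0, 1e-4)
    else mu + rnorm(5, 0, sigma)
  }))
  cal <- calibration_data(rep(conc, each = 5), resp)
  lod <- lod_iupac(cal, p)
  sig_conc <- attr(lod, "significant_concentration")
  grp <- cal$data$response[cal$data$concentration == sig_conc]
  expect_equal(as.numeric(lod),
               3.3 * sd(grp) / abs(slope_4pl(p, sig_conc)),
               tolerance = 1e-12)
  ## LOD scales linearly with the injected SD at fixed slope
  resp2 <- unlist(lapply(conc, function(x) {
    mu <- predict_4pl(p, x)
    if (x == 1) rep(mu, 5) + rnorm(5, 0, 1e-4) else mu + rnorm(5, 0, 2 * sigma)
  }))
  ## same slope, doubled noise: expect roughly doubled LOD on average;
  ## assert the deterministic identity instead on the realized SD
  cal2 <- calibration_data(rep(conc, each = 5), resp2)
  lod2 <- tryCatch(lod_iupac(cal2, p), error = function(e) NULL)
  if (!is.null(lod2)) {
    g2 <- cal2$data$response[cal2$data$concentration ==
                               attr(lod2, "significant_concentration")]
    expect_equal(as.numeric(lod2),
                 3.3 * sd(g2) /
                   abs(slope_4pl(p, attr(lod2, "significant_concentration"))),
                 tolerance = 1e-12)
  }
})

test_that("zero within-group scatter drives the LOD to zero", {
  p <- echem_4pl()
  conc <- c(1, 10, 100, 1000)
  resp <- unlist(lapply(conc, function(x) {
    mu <- predict_4pl(p, x)
    if (x == 1) mu + c(-1e-6, 0, 1e-6) else rep(mu, 3)
  }))
  cal <- calibration_data(rep(conc, each = 3), resp)
  expect_lt(as.numeric(lod_iupac(cal, p)), 1e-10)
})

test_that("LOD is undefined when no group separates from the reference", {
  p <- echem_4pl()
  set.seed(3)
  resp <- rnorm(20, mean = -14, sd = 0.2)
  cal <- calibration_data(rep(c(1, 3, 10, 30), each = 5), resp)
  expect_error(lod_iupac(cal, p), "undefined|significan")
})

test_that("SNR implements the background-corrected ratio", {
  expect_equal(snr(-20, -10, -20)$mean_snr, 1)
  ## constructed so numerator = 6.9 x denominator
  expect_equal(snr(-10 - 6.9, -10, -11)$mean_snr, 6.9)
  expect_error(snr(-20, -10, -10), "background")
  ## randomized triples vs the direct formula, plus additive-shift
  ## invariance
  set.seed(13)
  for (k in 1:25) {
    tgt <- runif(1, -30, -20); bg <- runif(1, -10, -5)
    intf <- runif(3, -15, -11)
    r <- snr(tgt, bg, intf)
    expect_equal(r$snr, (tgt - bg) / (intf - bg))
    shift <- runif(1, -5, 5)
    expect_equal(snr(tgt + shift, bg + shift, intf + shift)$snr, r$snr,
                 tolerance = 1e-12)
  }
})

test_that("Brown-Anson implements the printed surface-concentration formula", {
  expect_equal(as.numeric(brown_anson_gamma(0, 0.1, 0.1125)), 0)
  ## randomized inputs vs independent hand evaluation
  set.seed(17)
  for (k in 1:20) {
    I <- runif(1, 1, 50); v <- runif(1, 0.01, 0.5)
    ecsa <- runif(1, 0.05, 1); ag <- runif(1, 5, 20); Tk <- runif(1, 280, 320)
    got <- as.numeric(brown_anson_gamma(I, v, ecsa, ag, Tk))
    hand <- 4 * 8.314 * Tk * (I * ag * 1e-6) /
      ((ag / 100) * 96485^2 * v * ecsa) * 1e9
    expect_equal(got, hand, tolerance = 1e-12)
  }
  ## the printed-input evaluation is reported with its unit reading;
  ## the package documents the computed value alongside the published
  ## 25.1 nmol/cm^2 rather than forcing agreement
  g <- brown_anson_gamma(I_ox = 12.6, v = 0.1, ECSA = 0.1125,
                         A_g_mm2 = 12.56, T_K = 298)
  expect_equal(as.numeric(g),
               4 * 8.314 * 298 * (12.6 * 12.56 * 1e-6) /
                 (0.1256 * 96485^2 * 0.1 * 0.1125) * 1e9,
               tolerance = 1e-12)
  expect_match(attr(g, "interpretation"), "current density")
  expect_error(brown_anson_gamma(12.6, -0.1, 0.1125), "positive")
})
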