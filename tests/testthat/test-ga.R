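make_front <- function(err_mat, D = NULL) {
  lapply(seq_len(nrow(err_mat)), function(k)
    list(params = interface_params(
           D = if (is.null(D)) 1e-5 else D[k], k0 = 1e-3,
           alpha = 0.5, ECSA = 0.1),
         errors = structure(setNames(err_mat[k, ],
                                     c("dI_ox", "dI_red", "dE_pp")),
                            class = c("error_vector", "numeric"))))
}

test_that("elitist selection picks the point nearest the error-space origin", {
  f1 <- make_front(matrix(c(1, 1, 1), nrow = 1))
  expect_equal(select_elitist(f1)$norm, sqrt(3))
  f2 <- make_front(rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(select_elitist(f2)$norm, sqrt(3))
  expect_error(select_elitist(list()), "empty")
  ## ties broken by |dE_pp|, then lowest D
  f3 <- make_front(rbind(c(3, 0, 4), c(5, 0, 0)), D = c(1e-5, 1e-6))
  expect_equal(select_elitist(f3)$errors[["dE_pp"]], 0)
  f4 <- make_front(rbind(c(3, 4, 0), c(3, 4, 0)), D = c(2e-5, 1e-6))
  expect_equal(select_elitist(f4)$params$D, 1e-6)
})

test_that("elitist selection agrees with a brute-force minimum-norm scan", {
  set.seed(123)
  for (k in 1:200) {
    m <- matrix(runif(30, 0, 10) * sample(c(-1, 1), 30, TRUE), ncol = 3)
    front <- make_front(m)
    norms <- sqrt(rowSums(abs(m)^2))
    expect_equal(select_elitist(front)$norm, min(norms))
  }
})

test_that("a candidate equal to the generating truth scores near-zero errors", {
  ip <- bare_params()
  prot <- std_protocol()
  grid <- make_grid(domain_length(ip$D, prot), 250L)
  target <- simulate_cv(ip, std_couple(), prot, grid,
                        substeps_per_Estep = 5L)
  ev <- evaluate_candidate(ip, extract_features(target), std_couple(),
                           prot, grid, substeps_per_Estep = 5L)
  expect_lt(error_norm(ev), 1e-10)
})

test_that("sluggish kinetics against a reversible target widen the separation error", {
  rev <- interface_params(D = 1e-5, k0 = 1, alpha = 0.5, ECSA = 0.1256)
  prot <- std_protocol()
  grid <- make_grid(domain_length(1e-5, prot), 250L)
  target_f <- extract_features(simulate_cv(rev, std_couple(), prot, grid,
                                           substeps_per_Estep = 5L))
  slow <- interface_params(D = 1e-5, k0 = 1e-4, alpha = 0.5, ECSA = 0.1256)
  ev <- evaluate_candidate(slow, target_f, std_couple(), prot, grid,
                           substeps_per_Estep = 5L)
  ## simulated E_pp exceeds the reversible target's, so the signed error
  ## is large and negative, large in magnitude
  expect_gt(abs(ev[["dE_pp"]]), 50)
})

test_that("a failing candidate is penalized, not fatal", {
  f <- cv_features(1e-5, -1e-5, -0.2, -0.3)
  ## zero bulk concentration produces a featureless trace upstream
  expect_warning(
    ev <- evaluate_candidate(bare_params(), f, redox_couple(c_b = 0),
                             std_protocol(),
                             make_grid(0.07, 100L), substeps_per_Estep = 2L),
    "penalized")
  expect_true(all(!is.finite(as.numeric(ev))))
})

test_that("bounds collapsed to a point return that point with its errors", {
  ip <- bare_params()
  prot <- std_protocol()
  grid <- make_grid(domain_length(ip$D, prot), 200L)
  target <- simulate_cv(ip, std_couple(), prot, grid,
                        substeps_per_Estep = 4L)
  b <- parameter_bounds(D = c(ip$D, ip$D), k0 = c(ip$k0, ip$k0),
                        alpha = c(0.5, 0.5), ECSA = c(ip$ECSA, ip$ECSA))
  res <- invert_parameters(target, b, ga_config(n_repeats = 1L),
                           std_couple(), prot, grid,
                           substeps_per_Estep = 4L)
  expect_equal(res$estimate$D, ip$D)
  expect_equal(res$estimate$k0, ip$k0)
  expect_lt(res$elitist$norm, 1e-10)
})

test_that("inversion is deterministic under a fixed seed", {
  ip <- bare_params()
  prot <- std_protocol()
  grid <- make_grid(domain_length(ip$D, prot), 150L)
  target <- simulate_cv(ip, std_couple(), prot, grid,
                        substeps_per_Estep = 3L)
  b <- parameter_bounds(D = c(1e-6, 1e-4), k0 = c(1e-4, 1e-1),
                        alpha = c(0.5, 0.5), ECSA = c(0.1256, 0.1256))
  cfg <- ga_config(pop_size = 12L, generations = 4L, n_repeats = 2L,
                   seed = 42L)
  r1 <- invert_parameters(target, b, cfg, std_couple(), prot, grid,
                          substeps_per_Estep = 3L)
  r2 <- invert_parameters(target, b, cfg, std_couple(), prot, grid,
                          substeps_per_Estep = 3L)
  expect_identical(unlist(r1$estimate), unlist(r2$estimate))
  expect_identical(r1$history, r2$history)
})

test_that("reported parameters respect the bounds exactly", {
  ip <- bare_params()
  prot <- std_protocol()
  grid <- make_grid(domain_length(ip$D, prot), 150L)
  target <- simulate_cv(ip, std_couple(), prot, grid,
                        substeps_per_Estep = 3L)
  b <- parameter_bounds(D = c(5e-6, 2e-5), k0 = c(1e-3, 1e-2),
                        alpha = c(0.4, 0.6), ECSA = c(0.05, 0.5))
  res <- invert_parameters(target, b,
                           ga_config(pop_size = 12L, generations = 5L,
                                     n_repeats = 1L, seed = 1L),
                           std_couple(), prot, grid,
                           substeps_per_Estep = 3L)
  for (m in res$pareto_front) {
    p <- m$params
    expect_true(p$D >= b["lower", "D"] && p$D <= b["upper", "D"])
    expect_true(p$k0 >= b["lower", "k0"] && p$k0 <= b["upper", "k0"])
    expect_true(p$alpha >= b["lower", "alpha"] &&
                p$alpha <= b["upper", "alpha"])
    expect_true(p$ECSA >= b["lower", "ECSA"] && p$ECSA <= b["upper", "ECSA"])
  }
})

test_that("GA elitist matches an exhaustive log-grid search over (D, k0)", {
  ip <- bare_params()
  prot <- std_protocol()
  grid <- make_grid(domain_length(ip$D, prot), 150L)
  couple <- std_couple()
  target <- simulate_cv(ip, couple, prot, grid, substeps_per_Estep = 3L)
  tf <- extract_features(target)
  ## 40 x 40 log grid over one decade either side of truth
  Ds <- 10^seq(log10(ip$D) - 1, log10(ip$D) + 1, length.out = 40)
  k0s <- 10^seq(log10(ip$k0) - 1, log10(ip$k0) + 1, length.out = 40)
  norms <- matrix(NA_real_, 40, 40)
  for (a in 1:40) for (b_ in 1:40) {
    cand <- interface_params(D = Ds[a], k0 = k0s[b_], alpha = 0.5,
                             ECSA = ip$ECSA)
    norms[a, b_] <- error_norm(
      evaluate_candidate(cand, tf, couple, prot, grid,
                         substeps_per_Estep = 3L))
  }
  best <- which(norms == min(norms), arr.ind = TRUE)[1, ]
  bnd <- parameter_bounds(D = range(Ds), k0 = range(k0s),
                          alpha = c(0.5, 0.5),
                          ECSA = c(ip$ECSA, ip$ECSA))
  res <- invert_parameters(target, bnd,
                           ga_config(pop_size = 24L, generations = 25L,
                                     n_repeats = 1L, seed = 2L),
                           couple, prot, grid, substeps_per_Estep = 3L)
  cell <- diff(log10(Ds))[1]
  expect_lt(abs(log10(res$elitist$params$D) - log10(Ds[best["row"]])),
            cell * 1.5)
  expect_lt(abs(log10(res$elitist$params$k0) - log10(k0s[best["col"]])),
            cell * 1.5)
})

test_that("median recovery error shrinks as the GA budget grows", {
  ip <- bare_params()
  prot <- std_protocol()
  grid <- make_grid(domain_length(ip$D, prot), 150L)
  target <- simulate_cv(ip, std_couple(), prot, grid,
                        substeps_per_Estep = 3L)
  b <- parameter_bounds(D = c(1e-6, 1e-4), k0 = c(4.5e-4, 4.5e-2),
                        alpha = c(0.5, 0.5), ECSA = c(0.1256, 0.1256))
  err <- vapply(list(c(8L, 2L), c(16L, 8L), c(32L, 25L)), function(bud) {
    res <- invert_parameters(
      target, b, ga_config(pop_size = bud[1], generations = bud[2],
                           n_repeats = 1L, seed = 10L),
      std_couple(), prot, grid, substeps_per_Estep = 3L)
    abs(log10(res$estimate$D / ip$D)) + abs(log10(res$estimate$k0 / ip$k0))
  }, numeric(1))
  expect_true(err[3] <= err[1])
  expect_lt(err[3], 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(ga_config(pop_size = 4L), "pop_size")
  expect_error(ga_config(generations = 0L), "generations")
  expect_error(ga_config(n_repeats = 0L), "n_repeats")
  expect_error(parameter_bounds(D = c(1e-3, 1e-7)), "lower")
  expect_error(parameter_bounds(alpha = c(0, 0.7)), "alpha")
  expect_error(parameter_bounds(k0 = c(-1, 1)), "positive")
})
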