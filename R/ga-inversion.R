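#' Search bounds for the interface parameters
#'
#' Box constraints for the four-parameter inverse problem. Each entry is
#' `c(lower, upper)`; setting `lower == upper` collapses that dimension,
#' i.e. fixes the parameter and removes it from the search. Defaults span
#' the decades typical of carbon electrodes and nanocomposite films.
#'
#' @param D Bounds for the diffusion coefficient (cm^2/s).
#' @param k0 Bounds for the rate constant (cm/s).
#' @param alpha Bounds for the charge-transfer coefficient, within (0, 1).
#' @param ECSA Bounds for the active area (cm^2).
#' @return An object of class `parameter_bounds` (2 x 4 matrix).
#' @export
parameter_bounds <- function(D = c(1e-7, 1e-3), k0 = c(1e-5, 1),
                             alpha = c(0.3, 0.7), ECSA = c(0.01, 1)) {
  b <- cbind(D = D, k0 = k0, alpha = alpha, ECSA = ECSA)
  if (nrow(b) != 2L) stop("each bound must be c(lower, upper)")
  if (any(!is.finite(b))) stop("bounds must be finite")
  if (any(b[1, ] > b[2, ]))
    stop("lower bounds must not exceed upper bounds")
  if (b[1, "alpha"] <= 0 || b[2, "alpha"] >= 1)
    stop("alpha bounds must lie within (0, 1)")
  if (any(b[1, c("D", "k0", "ECSA")] <= 0))
    stop("D, k0, ECSA bounds must be strictly positive")
  rownames(b) <- c("lower", "upper")
  structure(b, class = c("parameter_bounds", class(b)))
}

#' Genetic-algorithm configuration
#'
#' Hyperparameters of the elitist non-dominated-sorting GA. Defaults are
#' sized so that one repeat of a two- or three-parameter inversion
#' completes in well under a minute on a single CPU with the compiled
#' forward model.
#'
#' @param pop_size Population size (even, >= 8).
#' @param generations Number of generations (>= 1).
#' @param p_crossover Simulated-binary-crossover probability per pair.
#' @param eta_crossover SBX distribution index.
#' @param p_mutation Per-gene polynomial-mutation probability; `NULL`
#'   means `1 / n_searched_parameters`.
#' @param eta_mutation Polynomial-mutation distribution index.
#' @param seed Base random seed; repeat `r` uses `seed + r`.
#' @param n_repeats Independent GA runs to aggregate (default 3).
#' @param log_scale Named logical: which parameters are searched on a
#'   log10 scale (default: D, k0, ECSA — they span decades).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 48L, generations = 60L,
                      p_crossover = 0.9, eta_crossover = 15,
                      p_mutation = NULL, eta_mutation = 20,
                      seed = 1L, n_repeats = 3L,
                      log_scale = c(D = TRUE, k0 = TRUE,
                                    alpha = FALSE, ECSA = TRUE)) {
  pop_size <- as.integer(pop_size)
  generations <- as.integer(generations)
  n_repeats <- as.integer(n_repeats)
  if (pop_size < 8L) stop("`pop_size` must be >= 8")
  if (pop_size %% 2L != 0L) pop_size <- pop_size + 1L
  if (generations < 1L) stop("`generations` must be >= 1")
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1")
  stopifnot(all(c("D", "k0", "alpha", "ECSA") %in% names(log_scale)))
  structure(
    list(pop_size = pop_size, generations = generations,
         p_crossover = p_crossover, eta_crossover = eta_crossover,
         p_mutation = p_mutation, eta_mutation = eta_mutation,
         seed = as.integer(seed), n_repeats = n_repeats,
         log_scale = log_scale[c("D", "k0", "alpha", "ECSA")]),
    class = "ga_config"
  )
}

#' Evaluate one candidate parameter set against experimental features
#'
#' Forward-simulates a CV at the candidate parameters, extracts the
#' feature triple, and returns the signed percent error vector against
#' the experimental features. A simulator or feature-extraction failure
#' yields an infinite-penalty error vector (with a warning) rather than
#' aborting the search.
#'
#' @param params An [interface_params()] candidate.
#' @param exp_features Experimental [cv_features()].
#' @param couple,protocol,grid Forward-model inputs (see [simulate_cv()]).
#' @param substeps_per_Estep Time sub-stepping for the forward model.
#' @return An [error_vector()] (possibly infinite).
#' @export
evaluate_candidate <- function(params, exp_features, couple, protocol,
                               grid, substeps_per_Estep = 10L) {
  tryCatch({
    tr <- simulate_cv(params, couple, protocol, grid,
                      substeps_per_Estep = substeps_per_Estep)
    error_vector(exp_features, extract_features(tr))
  }, error = function(e) {
    warning("candidate penalized: ", conditionMessage(e), call. = FALSE)
    structure(c(dI_ox = Inf, dI_red = Inf, dE_pp = Inf),
              class = c("error_vector", "numeric"))
  })
}

#' Select the elitist solution from a Pareto front
#'
#' The elitist is the front member closest to the origin of the
#' three-dimensional error space, i.e. with minimum Euclidean norm of
#' `(|dI_ox|, |dI_red|, |dE_pp|)`. Ties are broken by smallest `|dE_pp|`,
#' then by lowest `D`.
#'
#' @param front A nonempty list of `list(params = interface_params,
#'   errors = error_vector)` members.
#' @return The selected member (same structure, with `norm` added).
#' @export
select_elitist <- function(front) {
  if (length(front) == 0L) stop("empty Pareto front")
  norms <- vapply(front, function(m) error_norm(m$errors), numeric(1))
  depp <- vapply(front, function(m) abs(m$errors[["dE_pp"]]), numeric(1))
  Dval <- vapply(front, function(m) m$params$D, numeric(1))
  best <- order(norms, depp, Dval)[1L]
  out <- front[[best]]
  out$norm <- norms[best]
  out
}

## ---- NSGA-II machinery (objectives = |error| triple, minimized) ----

## fast non-dominated sort; obj is n x m matrix; returns integer ranks
.nds_rank <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  dom_count <- integer(n)
  dominates <- vector("list", n)
  for (p in seq_len(n)) {
    dp <- integer(0)
    for (q in seq_len(n)) {
      if (p == q) next
      le <- all(obj[p, ] <= obj[q, ])
      lt <- any(obj[p, ] < obj[q, ])
      ge <- all(obj[q, ] <= obj[p, ])
      gt <- any(obj[q, ] < obj[p, ])
      if (le && lt) dp <- c(dp, q)
      else if (ge && gt) dom_count[p] <- dom_count[p] + 1L
    }
    dominates[[p]] <- dp
  }
  front <- which(dom_count == 0L)
  r <- 1L
  while (length(front) > 0L) {
    rank[front] <- r
    nxt <- integer(0)
    for (p in front) {
      for (q in dominates[[p]]) {
        dom_count[q] <- dom_count[q] - 1L
        if (dom_count[q] == 0L) nxt <- c(nxt, q)
      }
    }
    front <- nxt
    r <- r + 1L
  }
  rank
}

.crowding <- function(obj) {
  n <- nrow(obj)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    d[o[1L]] <- d[o[n]] <- Inf
    span <- obj[o[n], m] - obj[o[1L], m]
    if (is.finite(span) && span > 0) {
      for (k in 2:(n - 1L))
        d[o[k]] <- d[o[k]] + (obj[o[k + 1L], m] - obj[o[k - 1L], m]) / span
    }
  }
  d
}

## SBX crossover on [0,1]^d
.sbx <- function(p1, p2, eta, p_cross) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) <= p_cross) {
    for (j in seq_along(p1)) {
      if (stats::runif(1) <= 0.5 && abs(p1[j] - p2[j]) > 1e-14) {
        u <- stats::runif(1)
        beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
                else (1 / (2 * (1 - u)))^(1 / (eta + 1))
        x1 <- 0.5 * ((1 + beta) * p1[j] + (1 - beta) * p2[j])
        x2 <- 0.5 * ((1 - beta) * p1[j] + (1 + beta) * p2[j])
        c1[j] <- min(1, max(0, x1))
        c2[j] <- min(1, max(0, x2))
      }
    }
  }
  list(c1, c2)
}

## polynomial mutation on [0,1]^d
.polymut <- function(x, eta, p_mut) {
  for (j in seq_along(x)) {
    if (stats::runif(1) <= p_mut) {
      u <- stats::runif(1)
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
               else 1 - (2 * (1 - u))^(1 / (eta + 1))
      x[j] <- min(1, max(0, x[j] + delta))
    }
  }
  x
}

## binary tournament on (rank, crowding)
.tournament <- function(rank, crowd) {
  i <- sample.int(length(rank), 2L)
  a <- i[1L]; b <- i[2L]
  if (rank[a] < rank[b]) a
  else if (rank[b] < rank[a]) b
  else if (crowd[a] > crowd[b]) a
  else b
}

## map unit-cube genotype to interface_params given bounds/log flags
.decode <- function(x, lo_t, hi_t, log_flag, fixed_vals, free_idx) {
  v <- fixed_vals
  if (length(free_idx) > 0L) {
    vt <- lo_t[free_idx] + x * (hi_t[free_idx] - lo_t[free_idx])
    v[free_idx] <- ifelse(log_flag[free_idx], 10^vt, vt)
  }
  interface_params(D = v[["D"]], k0 = v[["k0"]],
                   alpha = v[["alpha"]], ECSA = v[["ECSA"]])
}

## one NSGA-II run; returns list(front = list(params, errors), history)
.nsga2_run <- function(eval_fn, bounds, ga, verbose = FALSE) {
  nm <- c("D", "k0", "alpha", "ECSA")
  lo <- as.numeric(bounds["lower", nm]); names(lo) <- nm
  hi <- as.numeric(bounds["upper", nm]); names(hi) <- nm
  log_flag <- as.logical(ga$log_scale[nm]); names(log_flag) <- nm
  free_idx <- nm[lo < hi]
  fixed_vals <- lo  # collapsed dims sit at their (equal) bound
  lo_t <- ifelse(log_flag, log10(lo), lo); names(lo_t) <- nm
  hi_t <- ifelse(log_flag, log10(hi), hi); names(hi_t) <- nm
  d <- length(free_idx)
  N <- ga$pop_size
  p_mut <- if (is.null(ga$p_mutation)) 1 / max(1L, d) else ga$p_mutation

  if (d == 0L) {  # fully collapsed search space
    params <- .decode(numeric(0), lo_t, hi_t, log_flag, fixed_vals, free_idx)
    errors <- eval_fn(params)
    return(list(front = list(list(params = params, errors = errors)),
                history = error_norm(errors)))
  }

  pop <- matrix(stats::runif(N * d), nrow = N)
  decode_row <- function(x) .decode(x, lo_t, hi_t, log_flag,
                                    fixed_vals, free_idx)
  eval_pop <- function(P) {
    lst <- apply(P, 1L, function(x) eval_fn(decode_row(x)),
                 simplify = FALSE)
    do.call(rbind, lapply(lst, as.numeric))
  }
  errs <- eval_pop(pop)          # signed errors
  obj <- abs(errs)               # minimized magnitudes
  history <- numeric(ga$generations)

  for (g in seq_len(ga$generations)) {
    if (all(!is.finite(obj[, 1])))
      stop("convergence failure: every candidate penalized in generation ",
           g, " (check bounds and experimental features)")
    rank <- .nds_rank(obj)
    crowd <- numeric(N)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- .crowding(obj[idx, , drop = FALSE])
    }
    ## variation
    child <- matrix(0, nrow = N, ncol = d)
    k <- 1L
    while (k < N) {
      a <- .tournament(rank, crowd); b <- .tournament(rank, crowd)
      off <- .sbx(pop[a, ], pop[b, ], ga$eta_crossover, ga$p_crossover)
      child[k, ] <- .polymut(off[[1L]], ga$eta_mutation, p_mut)
      child[k + 1L, ] <- .polymut(off[[2L]], ga$eta_mutation, p_mut)
      k <- k + 2L
    }
    errs_c <- eval_pop(child)
    obj_c <- abs(errs_c)
    ## environmental selection on the combined population
    pop_all <- rbind(pop, child)
    errs_all <- rbind(errs, errs_c)
    obj_all <- rbind(obj, obj_c)
    rank_all <- .nds_rank(obj_all)
    keep <- integer(0)
    r <- 1L
    while (length(keep) < N) {
      idx <- which(rank_all == r)
      if (length(keep) + length(idx) <= N) {
        keep <- c(keep, idx)
      } else {
        cd <- .crowding(obj_all[idx, , drop = FALSE])
        keep <- c(keep, idx[order(-cd)][seq_len(N - length(keep))])
      }
      r <- r + 1L
    }
    pop <- pop_all[keep, , drop = FALSE]
    errs <- errs_all[keep, , drop = FALSE]
    obj <- obj_all[keep, , drop = FALSE]
    history[g] <- min(sqrt(rowSums(obj^2)))
    if (verbose)
      message(sprintf("  gen %3d: best |error| norm = %.4g %%", g,
                      history[g]))
  }

  rank <- .nds_rank(obj)
  idx <- which(rank == 1L)
  idx <- idx[!duplicated(round(obj[idx, , drop = FALSE], 10))]
  front <- lapply(idx, function(k) {
    list(params = decode_row(pop[k, ]),
         errors = structure(stats::setNames(errs[k, ],
                                            c("dI_ox", "dI_red", "dE_pp")),
                            class = c("error_vector", "numeric")))
  })
  list(front = front, history = history)
}

#' Invert a voltammogram for the interface parameters
#'
#' Runs the elitist non-dominated-sorting GA on the bounded
#' multi-objective problem: minimize the magnitudes of the three percent
#' relative errors `(dI_ox, dI_red, dE_pp)` between the experimental
#' features and forward simulations over `(D, k0, alpha, ECSA)`. After
#' each repeat converges, the Pareto-front member closest to the origin
#' of the error space is taken as that run's elitist; the headline
#' estimate is the per-parameter median over `n_repeats` independent
#' repeats (repeat `r` is seeded with `seed + r`), and the run-to-run
#' dispersion (max relative deviation from the median) is reported.
#'
#' @param exp A measured [cv_trace()] or precomputed [cv_features()].
#' @param bounds A [parameter_bounds()]; collapse a dimension
#'   (`lower == upper`) to fix that parameter.
#' @param ga A [ga_config()].
#' @param couple,protocol,grid Forward-model inputs; if `grid` is `NULL`
#'   it is built from the upper `D` bound so the domain is conservative
#'   for every candidate.
#' @param substeps_per_Estep Forward-model time sub-stepping.
#' @param verbose Log generation-wise best error norms.
#' @return An object of class `inversion_result` with fields `estimate`
#'   (median [interface_params()]), `elitist` (best single-run member),
#'   `pareto_front` (that run's front), `per_run_elitists`, `dispersion`
#'   (named, relative), and `history` (per-run best-norm traces).
#' @export
invert_parameters <- function(exp, bounds, ga = ga_config(), couple,
                              protocol, grid = NULL,
                              substeps_per_Estep = 10L, verbose = FALSE) {
  stopifnot(inherits(bounds, "parameter_bounds"), inherits(ga, "ga_config"))
  exp_features <- if (inherits(exp, "cv_features")) exp
                  else extract_features(exp)
  if (is.null(grid))
    grid <- make_grid(domain_length(bounds["upper", "D"], protocol), 500L)
  eval_fn <- function(params)
    evaluate_candidate(params, exp_features, couple, protocol, grid,
                       substeps_per_Estep = substeps_per_Estep)

  runs <- vector("list", ga$n_repeats)
  for (r in seq_len(ga$n_repeats)) {
    set.seed(ga$seed + r)
    if (verbose) message(sprintf("repeat %d/%d (seed %d)", r,
                                 ga$n_repeats, ga$seed + r))
    runs[[r]] <- .nsga2_run(eval_fn, bounds, ga, verbose = verbose)
  }
  elitists <- lapply(runs, function(x) select_elitist(x$front))
  norms <- vapply(elitists, `[[`, numeric(1), "norm")
  best_run <- which.min(norms)

  par_mat <- t(vapply(elitists, function(e)
    unlist(e$params[c("D", "k0", "alpha", "ECSA")]), numeric(4)))
  med <- apply(par_mat, 2L, stats::median)
  disp <- apply(par_mat, 2L, function(col) {
    m <- stats::median(col)
    if (m == 0) 0 else max(abs(col - m) / abs(m))
  })
  estimate <- interface_params(D = med[["D"]], k0 = med[["k0"]],
                               alpha = med[["alpha"]], ECSA = med[["ECSA"]])
  structure(
    list(estimate = estimate,
         elitist = elitists[[best_run]],
         pareto_front = runs[[best_run]]$front,
         per_run_elitists = elitists,
         dispersion = disp,
         history = lapply(runs, `[[`, "history")),
    class = "inversion_result"
  )
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("Inverse-learning result (median of",
      length(x$per_run_elitists), "repeats):\n")
  print(x$estimate)
  cat(sprintf("  best-run |error| norm: %.4g %%\n", x$elitist$norm))
  cat("  run-to-run dispersion:",
      paste(sprintf("%s %.1f%%", names(x$dispersion),
                    100 * x$dispersion), collapse = ", "), "\n")
  invisible(x)
}
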