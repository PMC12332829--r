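#' Four-parameter logistic (4PL) dose-response model
#'
#' `y = d + (a - d) / (1 + (x / c)^b)` with asymptotic minimum `a`, Hill
#' slope `b`, inflection point (EC50) `c`, and asymptotic maximum `d`.
#' By construction `y(c) = (a + d) / 2`.
#'
#' @param a,b,c,d Model parameters; `c > 0`.
#' @param r2 Optional goodness of fit carried from [fit_4pl()].
#' @return An object of class `four_pl`.
#' @export
four_pl <- function(a, b, c, d, r2 = NA_real_) {
  if (!all(is.finite(c(a, b, c, d)))) stop("4PL parameters must be finite")
  if (c <= 0) stop("EC50 `c` must be strictly positive")
  if (b == 0) stop("Hill slope `b` must be nonzero")
  structure(list(a = a, b = b, c = c, d = d, r2 = r2), class = "four_pl")
}

#' @export
print.four_pl <- function(x, ...) {
  cat(sprintf("4PL: a = %.4g, b = %.4g, c (EC50) = %.4g, d = %.4g", x$a,
              x$b, x$c, x$d))
  if (is.finite(x$r2)) cat(sprintf("  (R^2 = %.4f)", x$r2))
  cat("\n")
  invisible(x)
}

#' Evaluate the 4PL model
#'
#' @param params A [four_pl()].
#' @param x Concentration(s), > 0.
#' @return Predicted response(s).
#' @export
predict_4pl <- function(params, x) {
  stopifnot(inherits(params, "four_pl"))
  if (any(x <= 0)) stop("concentrations must be > 0")
  with(params, d + (a - d) / (1 + (x / c)^b))
}

#' Invert the 4PL model
#'
#' Solves `y = d + (a - d)/(1 + (x/c)^b)` for concentration:
#' `x = c * ((a - d)/(y - d) - 1)^(1/b)`.
#'
#' @param params A [four_pl()].
#' @param y Response(s), strictly between `a` and `d` (exclusive).
#' @return Concentration(s) in the units of `c`.
#' @export
invert_4pl <- function(params, y) {
  stopifnot(inherits(params, "four_pl"))
  lo <- min(params$a, params$d); hi <- max(params$a, params$d)
  if (any(y <= lo | y >= hi))
    stop(sprintf("response outside the open range (%g, %g)", lo, hi))
  with(params, c * ((a - d) / (y - d) - 1)^(1 / b))
}

#' Calibration table of replicate responses
#'
#' @param concentration Analyte concentrations (pg/mL), > 0, one per row.
#' @param response Replicate responses (current density in uA/mm^2 or
#'   absorbance in a.u.), same length.
#' @return An object of class `calibration_data`: the long table plus
#'   per-concentration group means, SDs and counts.
#' @export
calibration_data <- function(concentration, response) {
  stopifnot(length(concentration) == length(response))
  if (any(!is.finite(concentration)) || any(!is.finite(response)))
    stop("calibration values must be finite")
  if (any(concentration <= 0))
    stop("concentrations must be > 0 (log-scale dose axis)")
  tab <- data.frame(concentration = concentration, response = response)
  grp <- split(tab$response, tab$concentration)
  groups <- data.frame(
    concentration = as.numeric(names(grp)),
    mean = vapply(grp, mean, numeric(1)),
    sd = vapply(grp, function(x) if (length(x) > 1L) sd(x) else 0,
                numeric(1)),
    n = lengths(grp),
    row.names = NULL
  )
  groups <- groups[order(groups$concentration), ]
  structure(list(data = tab, groups = groups), class = "calibration_data")
}

#' Fit the 4PL calibration model
#'
#' Levenberg-Marquardt least squares of the 4PL model on the
#' per-concentration group means. Internally the dose axis is
#' log-transformed for conditioning (`(x/c)^b = exp(b * (log x - log c))`)
#' and parameters are reported on the natural scale. Starting values are
#' self-derived from the response extremes and the mid-response
#' concentration; a few jittered restarts guard against poor starts.
#'
#' @param data A [calibration_data()] (>= 4 distinct concentrations), or
#'   a data frame with `concentration` and `response` columns.
#' @param init Optional [four_pl()] starting values.
#' @return A [four_pl()] with `r2` filled in (computed on group means).
#' @examples
#' truth <- four_pl(a = -15.2, b = -0.64, c = 8.92, d = -12.5)
#' x <- 10^seq(0, 3, length.out = 8)
#' fit_4pl(calibration_data(x, predict_4pl(truth, x)))
#' @export
fit_4pl <- function(data, init = NULL) {
  if (is.data.frame(data))
    data <- calibration_data(data$concentration, data$response)
  stopifnot(inherits(data, "calibration_data"))
  g <- data$groups
  if (nrow(g) < 4L)
    stop("need >= 4 distinct concentrations for a 4-parameter fit")
  y <- g$mean; lx <- log(g$concentration)
  if (diff(range(y)) <= .Machine$double.eps * max(1, max(abs(y))))
    stop("flat responses: 4PL slope is unidentifiable")

  if (is.null(init)) {
    ## self-start: asymptotes from the dose-ordered extremes, EC50 from
    ## the concentration nearest mid-response, slope sign from the trend
    y_lo <- y[1L]; y_hi <- y[nrow(g)]
    mid <- (max(y) + min(y)) / 2
    c0 <- g$concentration[which.min(abs(y - mid))]
    increasing <- y_hi > y_lo
    ## in Eq 7, x -> 0 gives y -> d for b < 0 and y -> a for b > 0
    if (increasing) init <- four_pl(a = max(y), b = 1.5, c = c0, d = min(y))
    else            init <- four_pl(a = min(y), b = -1,  c = c0, d = max(y))
  }

  model <- response ~ d + (a - d) / (1 + exp(b * (lconc - lc)))
  df <- data.frame(response = y, lconc = lx)
  starts <- list(c(a = init$a, b = init$b, lc = log(init$c), d = init$d))
  ## jittered restarts in case the self-start lands badly
  for (k in 1:4) {
    s <- starts[[1L]]
    starts[[k + 1L]] <- s * (1 + 0.2 * sin(seq_along(s) * k)) +
      c(0, 0.2 * k * sign(s[["b"]]), 0.1 * k, 0)
  }
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(model, data = df, start = as.list(s),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("4PL fit did not converge after restarts")
  cf <- coef(fit)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  four_pl(a = cf[["a"]], b = cf[["b"]], c = exp(cf[["lc"]]), d = cf[["d"]],
          r2 = 1 - ss_res / ss_tot)
}

#' 4PL local slope (d response / d concentration)
#'
#' @param params A [four_pl()].
#' @param x Concentration(s), > 0.
#' @return Derivative(s) of the response with respect to concentration.
#' @export
slope_4pl <- function(params, x) {
  stopifnot(inherits(params, "four_pl"))
  if (any(x <= 0)) stop("concentrations must be > 0")
  with(params, {
    u <- (x / c)^b
    -(a - d) * b * u / (x * (1 + u)^2)
  })
}

#' IUPAC limit of detection from a calibration table
#'
#' Finds the lowest concentration group whose replicate responses differ
#' significantly from the reference (lowest-concentration or blank)
#' group by a two-sided Welch t-test at `alpha`, then converts 3.3 times
#' that group's response standard deviation into concentration units via
#' the local slope of the fitted 4PL at that concentration:
#' `LOD = 3.3 * SD / |slope|`.
#'
#' @param data A [calibration_data()] whose significant group has >= 3
#'   replicates.
#' @param params A fitted [four_pl()] for the same data.
#' @param alpha Significance level (default 0.05).
#' @param factor The expansion factor (default 3.3).
#' @return LOD in concentration units, with attributes
#'   `significant_concentration`, `p_value`, `sd`, `slope`.
#' @export
lod_iupac <- function(data, params, alpha = 0.05, factor = 3.3) {
  stopifnot(inherits(data, "calibration_data"), inherits(params, "four_pl"))
  g <- data$groups
  if (nrow(g) < 2L) stop("need a reference group plus at least one more")
  ref_conc <- g$concentration[1L]
  ref <- data$data$response[data$data$concentration == ref_conc]
  hit <- NULL
  for (k in 2:nrow(g)) {
    conc <- g$concentration[k]
    resp <- data$data$response[data$data$concentration == conc]
    if (length(resp) < 2L || length(ref) < 2L) next
    pt <- tryCatch(t.test(resp, ref)$p.value, error = function(e) NA_real_)
    if (is.finite(pt) && pt < alpha) {
      hit <- list(conc = conc, resp = resp, p = pt)
      break
    }
  }
  if (is.null(hit))
    stop("LOD undefined: no concentration group differs significantly ",
         "from the reference group")
  if (length(hit$resp) < 3L)
    stop("significant group has fewer than 3 replicates")
  m <- slope_4pl(params, hit$conc)
  if (m == 0) stop("zero local 4PL slope at the significant concentration")
  lod <- factor * sd(hit$resp) / abs(m)
  structure(lod, significant_concentration = hit$conc, p_value = hit$p,
            sd = sd(hit$resp), slope = m)
}

#' Signal-to-noise ratio against interferents
#'
#' `SNR = (I_target - I_background) / (I_interferent - I_background)`
#' on (signed) reduction peak currents. With several interferents a
#' per-interferent vector and its mean are returned.
#'
#' @param I_target Response at the target analyte level.
#' @param I_background Background (lowest-level) response.
#' @param I_interferent Response(s) with interferent(s) present.
#' @return A list with `snr` (per interferent) and `mean_snr`.
#' @examples
#' snr(I_target = -20, I_background = -10, I_interferent = c(-11.4, -11.5))
#' @export
snr <- function(I_target, I_background, I_interferent) {
  stopifnot(length(I_target) == 1L, length(I_background) == 1L,
            length(I_interferent) >= 1L)
  den <- I_interferent - I_background
  if (any(den == 0))
    stop("interferent response equals background: SNR undefined")
  ratio <- (I_target - I_background) / den
  list(snr = ratio, mean_snr = mean(ratio))
}

#' Brown-Anson surface concentration
#'
#' Implements the surface-concentration relation
#' `gamma = 4 * R * T * I_ox / (A_g * F^2 * v) * 1 / ECSA` as printed,
#' under the unit interpretation: `I_ox` is supplied as a current density
#' in uA/mm^2 and converted to total current (A) via the geometric area
#' `A_g`; both areas enter in cm^2. The interpretation is recorded in the
#' result's `interpretation` attribute so reports can state it.
#'
#' @param I_ox Oxidation peak current density (uA/mm^2), > 0.
#' @param v Scan rate (V/s), > 0.
#' @param ECSA Electrochemically active surface area (cm^2), > 0.
#' @param A_g_mm2 Geometric area (mm^2), > 0 (default 12.56).
#' @param T_K Temperature (K), default 298.
#' @return Surface concentration in nmol/cm^2 (attribute
#'   `interpretation` documents the unit reading used).
#' @export
brown_anson_gamma <- function(I_ox, v, ECSA, A_g_mm2 = 12.56, T_K = 298) {
  vals <- c(I_ox = I_ox, v = v, ECSA = ECSA, A_g_mm2 = A_g_mm2, T_K = T_K)
  if (any(!is.finite(vals)) || any(vals[-1] <= 0) || I_ox < 0)
    stop("all Brown-Anson inputs must be positive (I_ox >= 0)")
  I_total_A <- I_ox * A_g_mm2 * 1e-6        # uA/mm^2 * mm^2 -> A
  A_g_cm2 <- A_g_mm2 / 100
  gamma_mol <- 4 * GAS_CONSTANT * T_K * I_total_A /
    (A_g_cm2 * FARADAY^2 * v) / ECSA         # mol / cm^2
  structure(gamma_mol * 1e9,
            interpretation = paste(
              "I_ox read as current density (uA/mm^2), converted to total",
              "current via A_g; areas in cm^2; gamma in nmol/cm^2"))
}
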