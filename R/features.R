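#' CV feature triple
#'
#' The three features used by the inverse learner: oxidation peak
#' current, reduction peak current (signed, negative under the IUPAC
#' convention), and peak-to-peak separation, with the peak potentials.
#'
#' @param I_ox Oxidation peak current (> 0).
#' @param I_red Reduction peak current (<= 0).
#' @param E_ox,E_red Peak potentials (V).
#' @param units Unit tag for the currents (`"A"` or `"uA_mm2"`).
#' @return An object of class `cv_features` with fields `I_ox`, `I_red`,
#'   `E_ox`, `E_red`, `E_pp`.
#' @export
cv_features <- function(I_ox, I_red, E_ox, E_red, units = "A") {
  vals <- c(I_ox, I_red, E_ox, E_red)
  if (!all(is.finite(vals))) stop("features must be finite")
  if (I_ox <= 0 || I_red > 0)
    stop("expected I_ox > 0 >= I_red under the anodic-positive convention")
  structure(
    list(I_ox = I_ox, I_red = I_red, E_ox = E_ox, E_red = E_red,
         E_pp = abs(E_ox - E_red), units = units),
    class = "cv_features"
  )
}

#' @export
print.cv_features <- function(x, ...) {
  cat(sprintf("CV features [%s]: I_ox = %.4g, I_red = %.4g, E_pp = %.1f mV\n",
              x$units, x$I_ox, x$I_red, 1000 * x$E_pp))
  invisible(x)
}

## quadratic refinement of a discrete extremum from its three-point
## neighbourhood; returns c(x, y) at the parabola vertex
.refine_peak <- function(xv, yv, j) {
  if (j <= 1L || j >= length(xv)) return(c(xv[j], yv[j]))
  y1 <- yv[j - 1L]; y2 <- yv[j]; y3 <- yv[j + 1L]
  den <- y1 - 2 * y2 + y3
  if (den == 0) return(c(xv[j], yv[j]))
  delta <- 0.5 * (y1 - y3) / den
  delta <- max(-1, min(1, delta))
  h <- xv[j + 1L] - xv[j]   # uniform E spacing within a sweep
  c(xv[j] + delta * h, y2 - 0.25 * (y1 - y3) * delta)
}

.extract_one_cycle <- function(E, i) {
  dE <- diff(E)
  anodic <- which(dE > 0)
  cathodic <- which(dE < 0)
  if (length(anodic) < 3L || length(cathodic) < 3L)
    stop("trace does not contain both an anodic and a cathodic sweep")
  seg <- function(idx) sort(unique(c(idx, idx + 1L)))
  ia <- seg(anodic); ic <- seg(cathodic)
  ja <- which.max(i[ia])
  jc <- which.min(i[ic])
  if (ja == 1L || ja == length(ia))
    stop("no interior oxidation peak on the anodic sweep (monotonic trace)")
  if (jc == 1L || jc == length(ic))
    stop("no interior reduction peak on the cathodic sweep (monotonic trace)")
  pa <- .refine_peak(E[ia], i[ia], ja)
  pc <- .refine_peak(E[ic], i[ic], jc)
  list(I_ox = pa[2], E_ox = pa[1], I_red = pc[2], E_red = pc[1])
}

#' Extract peak features from a CV trace
#'
#' Per cycle, the oxidation peak is the maximum current on the
#' anodic (positive-going) sweep and the reduction peak the minimum on
#' the cathodic sweep; peak position and height are refined by 3-point
#' quadratic interpolation around the discrete extremum. Features are
#' averaged across cycles. An optional moving-average filter (window in
#' samples) can be applied before the extrema search for noisy
#' experimental traces.
#'
#' @param trace A [cv_trace()] (or data frame with columns `t`, `E`, `i`,
#'   `cycle`) containing at least one full cycle.
#' @param smooth_window Moving-average window in samples (0 = none).
#' @param use_density If `TRUE`, extract features from `i_density`
#'   (uA/mm^2) instead of total current.
#' @return A [cv_features()].
#' @examples
#' tr <- simulate_cv(interface_params(1e-5, 4.5e-3, 0.5, 0.1256),
#'                   redox_couple(), cv_protocol())
#' extract_features(tr)
#' @export
extract_features <- function(trace, smooth_window = 0L, use_density = FALSE) {
  stopifnot(is.data.frame(trace))
  need <- c("E", "i", "cycle")
  if (!all(need %in% names(trace)))
    stop("trace must have columns E, i, cycle")
  cur <- if (use_density) trace$i_density else trace$i
  if (smooth_window > 1L) {
    k <- as.integer(smooth_window)
    cur <- stats::filter(cur, rep(1 / k, k), sides = 2)
    keep <- !is.na(cur)
    cur <- as.numeric(cur[keep])
    Ev <- trace$E[keep]; cyc <- trace$cycle[keep]
  } else {
    Ev <- trace$E; cyc <- trace$cycle
  }
  per <- lapply(split(seq_along(Ev), cyc), function(idx) {
    if (length(idx) < 7L) return(NULL)  # partial cycle fragments
    .extract_one_cycle(Ev[idx], cur[idx])
  })
  per <- Filter(Negate(is.null), per)
  if (length(per) == 0L) stop("no complete cycle found in trace")
  avg <- function(f) mean(vapply(per, `[[`, numeric(1), f))
  cv_features(I_ox = avg("I_ox"), I_red = avg("I_red"),
              E_ox = avg("E_ox"), E_red = avg("E_red"),
              units = if (use_density) "uA_mm2" else "A")
}

#' Relative-error vector between experimental and simulated features
#'
#' Componentwise percent relative errors
#' `100 * (exp - sim) / exp` for `I_ox`, `I_red` and `E_pp`. All three
#' are on the percent scale so the multi-objective search treats them
#' commensurately. Errors are signed; the optimizer minimizes their
#' absolute values.
#'
#' @param exp,sim [cv_features()] objects (experimental and simulated).
#' @return An object of class `error_vector`: named numeric
#'   `c(dI_ox, dI_red, dE_pp)` in percent.
#' @examples
#' a <- cv_features(50e-6, -60e-6, -0.25, -0.31)
#' error_vector(a, a)  # c(0, 0, 0)
#' @export
error_vector <- function(exp, sim) {
  stopifnot(inherits(exp, "cv_features"), inherits(sim, "cv_features"))
  if (exp$I_ox == 0 || exp$I_red == 0 || exp$E_pp == 0)
    stop("experimental features must be nonzero in all three components")
  ev <- c(dI_ox = 100 * (exp$I_ox - sim$I_ox) / exp$I_ox,
          dI_red = 100 * (exp$I_red - sim$I_red) / exp$I_red,
          dE_pp = 100 * (exp$E_pp - sim$E_pp) / exp$E_pp)
  structure(ev, class = c("error_vector", "numeric"))
}

#' Euclidean norm of an error vector
#'
#' Distance from the origin of the three-dimensional error space, on the
#' magnitudes of the components.
#'
#' @param ev An [error_vector()] (or numeric length 3).
#' @return Nonnegative scalar.
#' @export
error_norm <- function(ev) sqrt(sum(abs(as.numeric(ev))^2))
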