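#' @useDynLib cvinverse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm sd t.test coef predict residuals setNames
#' @importFrom utils modifyList read.csv write.csv head tail
NULL

## Physical constants (SI-with-cm unit system used throughout:
## A, V, s, cm, mol/cm^3).
#' Physical constants
#'
#' Faraday constant (A s/mol) and molar gas constant (J/mol/K) used by the
#' simulator and the Brown-Anson estimator.
#'
#' @format Named numeric scalars.
#' @name constants
#' @keywords internal
FARADAY <- 96485      # A s / mol
GAS_CONSTANT <- 8.314 # J / mol / K

#' Single-electron redox couple
#'
#' Describes the dissolved redox probe interrogating the sensor interface,
#' e.g. 10 mM hexaammineruthenium(III). The model is written for a
#' one-electron transfer; `n_electrons` is fixed at 1.
#'
#' @param c_b Bulk concentration of the oxidized species (mol/cm^3).
#'   10 mM corresponds to `1e-5` mol/cm^3.
#' @param E_f0 Formal potential of the couple vs the reference electrode (V).
#' @param T_K Temperature (K), default 298.
#'
#' @return An object of class `redox_couple`.
#' @examples
#' ru_hex <- redox_couple(c_b = 1e-5, E_f0 = -0.25)
#' @export
redox_couple <- function(c_b = 1e-5, E_f0 = -0.25, T_K = 298) {
  stopifnot(is.numeric(c_b), length(c_b) == 1L, is.finite(c_b))
  if (c_b < 0) stop("bulk concentration `c_b` must be >= 0")
  if (!is.numeric(T_K) || length(T_K) != 1L || !is.finite(T_K) || T_K <= 0)
    stop("temperature `T_K` must be a positive scalar")
  if (!is.numeric(E_f0) || length(E_f0) != 1L || !is.finite(E_f0))
    stop("formal potential `E_f0` must be a finite scalar")
  structure(
    list(c_b = c_b, E_f0 = E_f0, T_K = T_K, n_electrons = 1L),
    class = "redox_couple"
  )
}

#' Learnable interface parameters
#'
#' The four quantities the inverse learner estimates for a biosensing
#' interface: apparent diffusion coefficient, heterogeneous (standard)
#' rate constant, charge-transfer coefficient, and electrochemically
#' active surface area.
#'
#' @param D Apparent diffusion coefficient (cm^2/s), > 0.
#' @param k0 Heterogeneous rate constant (cm/s), > 0.
#' @param alpha Charge-transfer coefficient, in (0, 1).
#' @param ECSA Electrochemically active surface area (cm^2), > 0.
#'
#' @return An object of class `interface_params`.
#' @examples
#' bare <- interface_params(D = 1e-5, k0 = 4.5e-3, alpha = 0.5, ECSA = 0.1256)
#' @export
interface_params <- function(D, k0, alpha = 0.5, ECSA) {
  vals <- c(D = D, k0 = k0, alpha = alpha, ECSA = ECSA)
  if (!all(is.finite(vals))) stop("interface parameters must be finite")
  if (D <= 0) stop("`D` must be strictly positive")
  if (k0 <= 0) stop("`k0` must be strictly positive")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (ECSA <= 0) stop("`ECSA` must be strictly positive")
  structure(list(D = D, k0 = k0, alpha = alpha, ECSA = ECSA),
            class = "interface_params")
}

#' @export
print.interface_params <- function(x, ...) {
  cat("Interface parameters:\n")
  cat(sprintf("  D     = %.4g cm^2/s\n", x$D))
  cat(sprintf("  k0    = %.4g cm/s\n", x$k0))
  cat(sprintf("  alpha = %.4g\n", x$alpha))
  cat(sprintf("  ECSA  = %.4g cm^2\n", x$ECSA))
  invisible(x)
}

#' Cyclic voltammetry scan protocol
#'
#' A triangular potential programme between the sweep limits `E_L` and
#' `E_R`, starting at `E_start` and moving in `initial_direction`. The
#' default protocol mirrors a common biosensor characterization: window
#' -0.6 to +0.1 V, 10 mV recorded steps, 100 mV/s, starting at the
#' positive limit with a cathodic (negative-going) first sweep because
#' the bulk species is the oxidized probe.
#'
#' @param E_start Initial potential (V); must lie within `[E_L, E_R]`.
#' @param E_L,E_R Lower and upper sweep limits (V), `E_L < E_R`.
#' @param v Scan rate (V/s), > 0.
#' @param E_step Recorded potential increment (V), default 0.010.
#' @param n_cycles Number of full cycles, integer >= 1.
#' @param initial_direction `"negative"` or `"positive"`.
#'
#' @return An object of class `cv_protocol`.
#' @examples
#' prot <- cv_protocol(v = 0.1)
#' cv_duration(prot)
#' @export
cv_protocol <- function(E_start = 0.1, E_L = -0.6, E_R = 0.1, v = 0.1,
                        E_step = 0.010, n_cycles = 1L,
                        initial_direction = c("negative", "positive")) {
  initial_direction <- match.arg(initial_direction)
  if (!(E_L < E_R)) stop("`E_L` must be strictly less than `E_R`")
  if (E_start < E_L || E_start > E_R)
    stop("`E_start` must lie within [E_L, E_R]")
  if (v <= 0) stop("scan rate `v` must be > 0")
  if (E_step <= 0) stop("`E_step` must be > 0")
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) stop("`n_cycles` must be >= 1")
  structure(
    list(E_start = E_start, E_L = E_L, E_R = E_R, v = v, E_step = E_step,
         n_cycles = n_cycles, initial_direction = initial_direction),
    class = "cv_protocol"
  )
}

#' Total duration of a CV protocol
#'
#' One cycle takes `2 * (E_R - E_L) / v` seconds.
#'
#' @param protocol A [cv_protocol()].
#' @return Duration in seconds.
#' @export
cv_duration <- function(protocol) {
  stopifnot(inherits(protocol, "cv_protocol"))
  protocol$n_cycles * 2 * (protocol$E_R - protocol$E_L) / protocol$v
}

#' Triangular potential waveform E(t)
#'
#' The instantaneous applied potential of the CV experiment: a
#' piecewise-linear triangular wave with slope `+/- v`, reflecting at the
#' sweep limits, starting at `E_start` in the protocol's initial
#' direction.
#'
#' @param protocol A [cv_protocol()].
#' @param t Time(s) in seconds, vectorized; each must lie within
#'   `[0, cv_duration(protocol)]`.
#' @return Potential(s) in volts.
#' @examples
#' prot <- cv_protocol(E_start = 0.1, E_L = -0.6, E_R = 0.1, v = 0.1)
#' waveform(prot, c(0, 7, 14))  # 0.1, -0.6, 0.1
#' @export
waveform <- function(protocol, t) {
  stopifnot(inherits(protocol, "cv_protocol"), is.numeric(t))
  dur <- cv_duration(protocol)
  if (any(t < -1e-12 | t > dur + 1e-12))
    stop(sprintf("time outside protocol duration [0, %.6g s]", dur))
  W <- protocol$E_R - protocol$E_L
  d <- if (protocol$initial_direction == "negative") -1 else 1
  xi <- (protocol$E_start - protocol$E_L) + d * protocol$v * t
  m <- xi %% (2 * W)           # R modulo maps into [0, 2W) for any sign
  protocol$E_L + ifelse(m <= W, m, 2 * W - m)
}

#' Maximum diffusion domain length
#'
#' The simulation domain extends `L = 6 * sqrt(2 * D * |E_R - E_L| / v)`
#' from the electrode, i.e. six diffusion lengths for the time scale of a
#' full sweep, so the far-field boundary does not perturb the surface
#' flux.
#'
#' @param D Apparent diffusion coefficient (cm^2/s), > 0.
#' @param protocol A [cv_protocol()].
#' @return Domain length in cm.
#' @examples
#' domain_length(1e-5, cv_protocol())  # ~0.0710 cm
#' @export
domain_length <- function(D, protocol) {
  stopifnot(inherits(protocol, "cv_protocol"))
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("`D` must be a positive scalar")
  6 * sqrt(2 * D * abs(protocol$E_R - protocol$E_L) / protocol$v)
}

#' Uniform spatial grid
#'
#' Equally spaced nodes with node 1 at the electrode surface (z = 0) and
#' the last node at z = L (far field).
#'
#' @param L Domain length (cm), > 0.
#' @param n_points Number of grid points, >= 3 (default 500).
#' @return An object of class `spatial_grid` with fields `n_points`, `L`,
#'   `dz` and the node coordinates `z`.
#' @examples
#' make_grid(1.0, 501)$dz  # 0.002
#' @export
make_grid <- function(L, n_points = 500L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("domain length `L` must be a positive scalar")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 3L)
    stop("`n_points` must be an integer >= 3")
  dz <- L / (n_points - 1)
  structure(
    list(n_points = n_points, L = L, dz = dz,
         z = seq(0, L, length.out = n_points)),
    class = "spatial_grid"
  )
}
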