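#' Read a voltammogram from delimited text
#'
#' Expects a header `time_s,potential_V,current_A,cycle` (comma default,
#' tab tolerated) with optional `# key: value` metadata lines before the
#' header. CRLF and LF line endings are both accepted. Numeric content
#' round-trips losslessly with [write_voltammogram()].
#'
#' @param path File path.
#' @param A_g_mm2 Geometric area for current density; overridden by an
#'   `A_g_mm2` metadata line if present.
#' @return A [cv_trace()] with metadata in `attr(, "meta")`.
#' @export
read_voltammogram <- function(path, A_g_mm2 = 12.56) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  is_meta <- grepl("^\\s*#", lines)
  ## metadata must precede data; take the leading comment block
  n_lead <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- list()
  if (n_lead > 0L) {
    for (ln in lines[seq_len(n_lead)]) {
      kv <- sub("^\\s*#\\s*", "", ln)
      m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1L]]
      if (length(m) == 3L) {
        val <- suppressWarnings(as.numeric(m[3L]))
        meta[[trimws(m[2L])]] <- if (is.na(val)) trimws(m[3L]) else val
      }
    }
  }
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in ", path)
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  header <- trimws(strsplit(body[1L], sep, fixed = TRUE)[[1L]])
  need <- c("time_s", "potential_V", "current_A", "cycle")
  missing_cols <- setdiff(need, header)
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- read.csv(text = paste(body, collapse = "\n"), sep = sep,
                 check.names = FALSE)
  for (cn in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column '%s' at data line %d of %s",
                   cn, bad[1L] + 1L, path))
    df[[cn]] <- as.numeric(df[[cn]])
  }
  if ("A_g_mm2" %in% names(meta) && is.numeric(meta$A_g_mm2))
    A_g_mm2 <- meta$A_g_mm2
  ## enforce time order within cycles (potentiostat exports are sorted,
  ## but be safe)
  ord <- order(df$cycle, df$time_s)
  df <- df[ord, ]
  cv_trace(df$time_s, df$potential_V, df$current_A,
           as.integer(df$cycle), A_g_mm2 = A_g_mm2, meta = meta)
}

#' Write a voltammogram to delimited text
#'
#' @param trace A [cv_trace()].
#' @param path Output file path.
#' @param sep Field separator (`","` default, `"\t"` accepted).
#' @return `path`, invisibly.
#' @export
write_voltammogram <- function(trace, path, sep = ",") {
  stopifnot(inherits(trace, "cv_trace"))
  meta <- attr(trace, "meta")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta) > 0L) {
    for (k in names(meta))
      writeLines(sprintf("# %s: %s", k,
                         format(meta[[k]], digits = 15, trim = TRUE)), con)
  }
  writeLines(sprintf("# A_g_mm2: %s",
                     format(attr(trace, "A_g_mm2"), digits = 15)), con)
  writeLines(paste(c("time_s", "potential_V", "current_A", "cycle"),
                   collapse = sep), con)
  rows <- paste(format(trace$t, digits = 15, trim = TRUE, scientific = NA),
                format(trace$E, digits = 15, trim = TRUE, scientific = NA),
                format(trace$i, digits = 15, trim = TRUE, scientific = NA),
                trace$cycle, sep = sep)
  writeLines(rows, con)
  invisible(path)
}

#' Generate a synthetic voltammogram with measurement noise
#'
#' Runs the forward simulator and adds i.i.d. zero-mean Gaussian current
#' noise of standard deviation `noise_sd` (in A), reproducibly for a
#' fixed seed. With `noise_sd = 0` the output is bitwise identical to
#' [simulate_cv()]. This is the package's test-fixture backbone,
#' emulating quasi-reversible single-electron CV measurements of a
#' dissolved probe; it does not emulate capacitive background current,
#' ohmic drop, or drift.
#'
#' @param interface,couple,protocol,grid,substeps_per_Estep,A_g_mm2
#'   Forward-model inputs (see [simulate_cv()]).
#' @param noise_sd Current-noise standard deviation (A), >= 0.
#' @param seed Integer seed for the noise generator.
#' @return A [cv_trace()].
#' @export
generate_synthetic_cv <- function(interface, couple, protocol, grid = NULL,
                                  noise_sd = 0, seed = 1L,
                                  substeps_per_Estep = 10L,
                                  A_g_mm2 = 12.56) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  tr <- simulate_cv(interface, couple, protocol, grid,
                    substeps_per_Estep = substeps_per_Estep,
                    A_g_mm2 = A_g_mm2)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    noisy <- tr$i + rnorm(nrow(tr), 0, noise_sd)
    meta <- c(attr(tr, "meta"), list(noise_sd_A = noise_sd, seed = seed))
    tr <- cv_trace(tr$t, tr$E, noisy, tr$cycle,
                   A_g_mm2 = attr(tr, "A_g_mm2"), meta = meta)
  }
  tr
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Load a run configuration
#'
#' Reads a YAML configuration describing the redox couple, scan
#' protocol, grid, geometry, GA settings and synthesis noise, validating
#' every field against the type invariants. Unknown top-level or nested
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return An object of class `run_config`: a list with elements
#'   `couple`, `protocol`, `n_points`, `A_g_mm2`, `bounds`, `ga`,
#'   `noise_sd`, `substeps_per_Estep`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param x A named list with the structure written by
#'   [write_run_config()].
#' @export
as_run_config <- function(x) {
  known <- c("couple", "protocol", "grid", "geometry", "ga", "noise")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  chk <- function(section, allowed) {
    extra <- setdiff(names(section), allowed)
    if (length(extra) > 0L)
      stop("unknown config key(s): ", paste(extra, collapse = ", "))
    section
  }
  cp <- chk(x$couple, c("c_b", "E_f0", "T_K"))
  couple <- do.call(redox_couple, modifyList(
    list(c_b = 1e-5, E_f0 = -0.25, T_K = 298), as.list(cp)))
  pr <- chk(x$protocol, c("E_start", "E_L", "E_R", "v", "E_step",
                          "n_cycles", "initial_direction"))
  protocol <- do.call(cv_protocol, as.list(pr))
  gr <- chk(x$grid, "n_points")
  n_points <- if (is.null(gr$n_points)) 500L else as.integer(gr$n_points)
  ge <- chk(x$geometry, "A_g_mm2")
  A_g_mm2 <- if (is.null(ge$A_g_mm2)) 12.56 else as.numeric(ge$A_g_mm2)
  if (A_g_mm2 <= 0) stop("geometric area must be > 0")
  ga_sec <- chk(x$ga, c("bounds", "pop_size", "generations", "seed",
                        "n_repeats", "p_crossover", "eta_crossover",
                        "p_mutation", "eta_mutation"))
  bounds <- if (is.null(ga_sec$bounds)) parameter_bounds()
            else do.call(parameter_bounds, lapply(
              chk(ga_sec$bounds, c("D", "k0", "alpha", "ECSA")), as.numeric))
  ga_args <- as.list(ga_sec)[setdiff(names(ga_sec), "bounds")]
  ga <- do.call(ga_config, ga_args)
  no <- chk(x$noise, "sd")
  noise_sd <- if (is.null(no$sd)) 0 else as.numeric(no$sd)
  if (noise_sd < 0) stop("noise sd must be >= 0")
  structure(
    list(couple = couple, protocol = protocol, n_points = n_points,
         A_g_mm2 = A_g_mm2, bounds = bounds, ga = ga,
         noise_sd = noise_sd),
    class = "run_config"
  )
}

#' Write a run configuration
#'
#' Serializes a `run_config` to YAML such that
#' `read_run_config(write_run_config(cfg, path))` reproduces it.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  b <- config$bounds
  lst <- list(
    couple = list(c_b = config$couple$c_b, E_f0 = config$couple$E_f0,
                  T_K = config$couple$T_K),
    protocol = config$protocol[c("E_start", "E_L", "E_R", "v", "E_step",
                                 "n_cycles", "initial_direction")],
    grid = list(n_points = config$n_points),
    geometry = list(A_g_mm2 = config$A_g_mm2),
    ga = list(bounds = list(D = as.numeric(b[, "D"]),
                            k0 = as.numeric(b[, "k0"]),
                            alpha = as.numeric(b[, "alpha"]),
                            ECSA = as.numeric(b[, "ECSA"])),
              pop_size = config$ga$pop_size,
              generations = config$ga$generations,
              p_crossover = config$ga$p_crossover,
              eta_crossover = config$ga$eta_crossover,
              eta_mutation = config$ga$eta_mutation,
              seed = config$ga$seed,
              n_repeats = config$ga$n_repeats),
    noise = list(sd = config$noise_sd)
  )
  attr(lst$protocol, "class") <- NULL
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}
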