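# 1:1 MO:RNA hybridization kinetics, as measured by label-free biosensors
# (biolayer interferometry). Association follows R(t) = Req (1 - e^(-k_obs t))
# with k_obs = k_on * C + k_off and Req = Rmax * C / (C + K_d); dissociation
# decays exponentially at k_off. The kinetic K_d is k_off / k_on; the
# equilibrium K_d comes from fitting the binding isotherm of plateau
# responses versus concentration.

#' Simulate a 1:1 binding sensorgram
#'
#' Generates a seed-deterministic association/dissociation trace under the
#' 1:1 model with optional Gaussian noise, for parameter-recovery testing.
#'
#' @param k_on association rate constant, 1/(M s).
#' @param k_off dissociation rate constant, 1/s.
#' @param Rmax maximal instrument response.
#' @param concentration MO concentration, molar.
#' @param times strictly increasing time points, seconds.
#' @param association_end time at which dissociation starts (default: the
#'   midpoint of the trace).
#' @param noise_sd Gaussian noise SD in response units (default 0).
#' @param seed integer seed used when noise is added.
#' @return Object of class `sensorgram`: list with `concentration`, `times`,
#'   `response`, `association_end`.
#' @export
simulate_sensorgram <- function(k_on, k_off, Rmax, concentration, times,
                                association_end = NULL, noise_sd = 0,
                                seed = 1L) {
  stopifnot(k_on > 0, k_off > 0, Rmax > 0, concentration > 0)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(association_end)) association_end <- times[ceiling(length(times) / 2)]
  kd <- k_off / k_on
  k_obs <- k_on * concentration + k_off
  req <- Rmax * concentration / (concentration + kd)
  assoc <- times <= association_end
  resp <- numeric(length(times))
  resp[assoc] <- req * (1 - exp(-k_obs * times[assoc]))
  r_end <- req * (1 - exp(-k_obs * association_end))
  resp[!assoc] <- r_end * exp(-k_off * (times[!assoc] - association_end))
  if (noise_sd > 0) {
    resp <- resp + with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  }
  structure(list(concentration = concentration, times = times,
                 response = resp, association_end = association_end),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("<sensorgram> C = %.3g M, %d points, association ends at %.0f s\n",
              x$concentration, length(x$times), x$association_end))
  invisible(x)
}

# Self-starting exponential fit helpers -------------------------------------

.exp_start <- function(times, response, rising) {
  y0 <- response[1L]
  A <- if (rising) max(response) - y0 else y0 - min(response)
  if (A <= 0) stop("no exponential signal")
  # log-linearized early slope for the rate
  span <- max(response) - min(response)
  frac <- if (rising) 1 - (response - y0) / (A * 1.05)
          else (response - min(response) + 0.05 * span) / (A * 1.05)
  ok <- which(is.finite(frac) & frac > 0.05)
  ok <- ok[seq_len(min(length(ok), max(5L, length(ok) %/% 2)))]
  k0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(frac[ok]) ~ times[ok]))[2L]
    max(abs(sl), 1e-6)
  }, error = function(e) 1 / max(times))
  c(y0 = y0, A = A, k = unname(k0))
}

.fit_exponential <- function(times, response, rising) {
  if (length(times) < 5L) stop("need >= 5 time points")
  if (!all(is.finite(response))) stop("response must be finite")
  if (stats::sd(response) == 0) stop("no exponential signal")
  st <- .exp_start(times, response, rising)
  form <- if (rising) response ~ y0 + A * (1 - exp(-k * times))
          else response ~ y0 + A * exp(-k * times)
  dat <- data.frame(times = times, response = response)
  best <- NULL
  for (mult in c(1, 0.1, 10, 0.01, 100)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat,
                        start = list(y0 = st[["y0"]], A = st[["A"]],
                                     k = st[["k"]] * mult),
                        lower = c(-Inf, 0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) best <- fit
      if (stats::deviance(fit) <= stats::deviance(best) + 1e-12) break
    }
  }
  if (is.null(best)) stop("exponential fit did not converge")
  cf <- stats::coef(best)
  list(Y0 = unname(cf["y0"]), A = unname(cf["A"]), k = unname(cf["k"]),
       residual_sd = sqrt(stats::deviance(best) / max(1, length(times) - 3)))
}

#' Fit the association phase of a sensorgram
#'
#' Nonlinear least-squares fit of `Y = Y0 + A (1 - exp(-k_obs t))` with
#' self-starting initial values (Y0 from the first response, A from the
#' range, rate from the log-linearized early slope).
#'
#' @param times,response association-phase time series.
#' @return List with `Y0`, `A`, `k_obs`, `residual_sd`.
#' @export
fit_association <- function(times, response) {
  f <- .fit_exponential(times, response, rising = TRUE)
  list(Y0 = f$Y0, A = f$A, k_obs = f$k, residual_sd = f$residual_sd)
}

#' Fit the dissociation phase of a sensorgram
#'
#' Nonlinear least-squares fit of `Y = Y0 + A exp(-k_off t)`.
#'
#' @param times,response dissociation-phase time series (time measured from
#'   the start of dissociation).
#' @return List with `Y0`, `A`, `k_off`, `residual_sd`.
#' @export
fit_dissociation <- function(times, response) {
  f <- .fit_exponential(times, response, rising = FALSE)
  list(Y0 = f$Y0, A = f$A, k_off = f$k, residual_sd = f$residual_sd)
}

#' Association rate constant from observed rates versus concentration
#'
#' Ordinary least-squares regression of k_obs on concentration: the slope
#' estimates k_on and the intercept estimates k_off (reported for
#' diagnostics). Warns when k_obs is not non-decreasing in concentration.
#'
#' @param concentrations molar concentrations (>= 2 distinct values).
#' @param k_obs_values observed rate constants, 1/s.
#' @return List with `k_on` (slope), `intercept`.
#' @export
kon_from_kobs <- function(concentrations, k_obs_values) {
  if (length(unique(concentrations)) < 2L) {
    stop("need >= 2 distinct concentrations")
  }
  ord <- order(concentrations)
  if (any(diff(k_obs_values[ord]) < 0)) {
    warning("k_obs is not non-decreasing in concentration")
  }
  cf <- stats::coef(stats::lm(k_obs_values ~ concentrations))
  list(k_on = unname(cf[2L]), intercept = unname(cf[1L]))
}

#' Equilibrium dissociation constant from a binding isotherm
#'
#' Least-squares fit of `R = Rmax C / (K_d + C)` to plateau responses at
#' several concentrations. Warns when the concentrations poorly bracket the
#' fitted K_d.
#'
#' @param concentrations molar concentrations (>= 3).
#' @param plateau_responses steady-state responses.
#' @return List with `Kd` (molar) and `Rmax`.
#' @export
fit_equilibrium_kd <- function(concentrations, plateau_responses) {
  if (length(concentrations) < 3L) stop("need >= 3 concentrations")
  kd0 <- stats::median(concentrations)
  rmax0 <- max(plateau_responses) * 1.5
  fit <- minpack.lm::nlsLM(
    plateau_responses ~ Rmax * concentrations / (Kd + concentrations),
    start = list(Rmax = rmax0, Kd = kd0),
    lower = c(1e-12, 1e-15),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  kd <- unname(cf["Kd"])
  if (kd < min(concentrations) / 10 || kd > max(concentrations) * 10) {
    warning("poorly constrained: concentrations do not bracket the fitted Kd")
  }
  list(Kd = kd, Rmax = unname(cf["Rmax"]))
}

#' Fit the full 1:1 kinetic model to a set of sensorgrams
#'
#' Fits each sensorgram's association and dissociation phases, regresses
#' k_obs on concentration for k_on, averages the per-trace k_off, and
#' reports both the kinetic K_d (k_off / k_on) and the equilibrium K_d from
#' the plateau isotherm.
#'
#' @param sensorgrams list of [simulate_sensorgram]-style objects spanning
#'   several concentrations.
#' @return Object of class `kinetic_fit`: per-concentration table plus
#'   `k_on`, `k_off`, `Kd_kinetic`, `Kd_equilibrium`, `Rmax`.
#' @export
fit_kinetics <- function(sensorgrams) {
  per <- lapply(sensorgrams, function(sg) {
    assoc <- sg$times <= sg$association_end
    fa <- fit_association(sg$times[assoc], sg$response[assoc])
    fd <- fit_dissociation(sg$times[!assoc] - sg$association_end,
                           sg$response[!assoc])
    plateau <- fa$Y0 + fa$A
    data.frame(concentration = sg$concentration, Y0 = fa$Y0, A = fa$A,
               k_obs = fa$k_obs, k_off_trace = fd$k_off, plateau = plateau)
  })
  per <- do.call(rbind, per)
  per <- per[order(per$concentration), ]
  kon <- kon_from_kobs(per$concentration, per$k_obs)
  k_off <- mean(per$k_off_trace)
  eq <- fit_equilibrium_kd(per$concentration, per$plateau)
  structure(list(per_concentration = per, k_on = kon$k_on, k_off = k_off,
                 Kd_kinetic = k_off / kon$k_on, Kd_equilibrium = eq$Kd,
                 Rmax = eq$Rmax),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> k_on %.3g /M/s, k_off %.3g /s, Kd(kinetic) %.3g M, Kd(equilibrium) %.3g M, Rmax %.3g\n",
              x$k_on, x$k_off, x$Kd_kinetic, x$Kd_equilibrium, x$Rmax))
  invisible(x)
}

#' Morpholino molecular weight
#'
#' Default convention: 340 Da per morpholino residue (a 25-mer is 8,500 Da).
#' Per-base monomer masses may be supplied to override the flat value.
#'
#' @param seq_or_length an [oligo], a sequence string, or an integer length.
#' @param mass_per_base flat monomer mass in Da (default 340), or a named
#'   vector of per-base masses (names A, C, G, T).
#' @return Molecular weight in Da.
#' @export
mo_molecular_weight <- function(seq_or_length, mass_per_base = 340) {
  if (inherits(seq_or_length, "oligo")) {
    bases <- seq_or_length$residues
  } else if (is.character(seq_or_length)) {
    bases <- strsplit(toupper(seq_or_length), "")[[1L]]
  } else {
    n <- as.integer(seq_or_length)
    if (is.na(n) || n < 1L) stop("length must be >= 1")
    if (length(mass_per_base) > 1L) stop("per-base masses require a sequence")
    return(n * mass_per_base)
  }
  if (length(bases) < 1L) stop("length must be >= 1")
  if (length(mass_per_base) == 1L) return(length(bases) * mass_per_base)
  sum(mass_per_base[bases])
}

#' Concentration reached by injecting an MO dose into a spherical embryo
#'
#' Converts an injected dose (ng) to molarity inside a zygote approximated
#' as a sphere: `moles = dose / MW`, `volume = (pi/6) d^3`, concentration in
#' nM. Under the default mass convention, 0.75 ng of a 25-mer in a 0.8 mm
#' zygote gives about 330 nM, reproducing the ~300 nM working estimate.
#'
#' @param dose_ng injected dose in nanograms.
#' @param mo an [oligo], sequence string, or length in bases.
#' @param diameter_mm embryo diameter in millimeters.
#' @param mass_per_base passed to [mo_molecular_weight].
#' @return Concentration in nanomolar.
#' @examples
#' injection_concentration(0.75, 25, 0.8)  # ~329 nM
#' @export
injection_concentration <- function(dose_ng, mo, diameter_mm,
                                    mass_per_base = 340) {
  stopifnot(dose_ng > 0, diameter_mm > 0)
  mw <- mo_molecular_weight(mo, mass_per_base)
  moles <- dose_ng * 1e-9 / mw
  volume_l <- (pi / 6) * diameter_mm^3 * 1e-6   # mm^3 -> liters
  moles / volume_l * 1e9
}

#' Read a sensorgram CSV
#'
#' Expects columns `concentration_M`, `time_s`, `response` and optionally
#' `association_end_s`; one sensorgram per concentration.
#'
#' @param path CSV path.
#' @return List of `sensorgram` objects.
#' @export
read_sensorgrams <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("concentration_M", "time_s", "response")
  if (!all(need %in% colnames(tab))) {
    stop("sensorgram CSV needs columns concentration_M, time_s, response")
  }
  lapply(split(tab, tab$concentration_M), function(d) {
    d <- d[order(d$time_s), ]
    ae <- if ("association_end_s" %in% colnames(d)) d$association_end_s[1L]
          else d$time_s[ceiling(nrow(d) / 2)]
    structure(list(concentration = d$concentration_M[1L], times = d$time_s,
                   response = d$response, association_end = ae),
              class = "sensorgram")
  })
}
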