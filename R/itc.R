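#' ITC titration protocol
#'
#' Defaults follow the study protocol: peptide at 200 uM in the syringe
#' titrated into 20 uM binder in the cell, 10 ul injections every 180 s at
#' 25 C. The working cell volume of the instrument (VP-ITC) is 1.43 ml.
#' 27 injections bring the molar ratio to ~2.7 given the 10:1 concentration
#' ratio.
#'
#' @param cell_conc Cell (binder) concentration, M.
#' @param syringe_conc Syringe (titrant) concentration, M.
#' @param cell_volume Working cell volume, L.
#' @param n_injections Number of injections.
#' @param injection_volume Volume per injection, L (scalar or vector).
#' @param interval_s Spacing between injections, seconds.
#' @param temperature K.
#' @return List of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_conc = 20e-6, syringe_conc = 200e-6,
                         cell_volume = 1.43e-3, n_injections = 27L,
                         injection_volume = 10e-6, interval_s = 180,
                         temperature = 298.15) {
  stopifnot(cell_conc > 0, syringe_conc > 0, cell_volume > 0)
  vols <- rep_len(injection_volume, n_injections)
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume, injection_volumes = vols,
                 interval_s = interval_s, temperature = temperature),
            class = "itc_protocol")
}

#' One-site binding parameters
#'
#' @param n Stoichiometry (sites per cell binder).
#' @param Kd Dissociation constant, M (`Ka = 1/Kd`).
#' @param dH Binding enthalpy, cal/mol.
#' @param baseline Constant per-injection heat offset, ucal.
#' @return List of class `one_site_params` with fields `n`, `Ka`, `Kd`,
#'   `dH`, `baseline`.
#' @export
one_site_params <- function(n = 1, Kd = 0.22e-6, dH = -8000, baseline = 0) {
  if (n <= 0 || Kd <= 0) stop("n and Kd must be positive")
  structure(list(n = n, Ka = 1 / Kd, Kd = Kd, dH = dH, baseline = baseline),
            class = "one_site_params")
}

## Total concentrations in the cell after each injection under the standard
## perfusion (overflow) correction: each injection of volume v dilutes the
## cell contents by (1 - v/V0) and adds titrant v/V0 * syringe_conc.
cell_totals <- function(protocol) {
  V0 <- protocol$cell_volume
  M <- numeric(length(protocol$injection_volumes))
  X <- numeric(length(protocol$injection_volumes))
  m <- protocol$cell_conc
  x <- 0
  for (i in seq_along(protocol$injection_volumes)) {
    f <- protocol$injection_volumes[i] / V0
    m <- m * (1 - f)
    x <- x * (1 - f) + protocol$syringe_conc * f
    M[i] <- m; X[i] <- x
  }
  list(M = M, X = X)
}

## Equilibrium complex concentration for 1:1 mass action with site
## concentration S = n*M: the physically meaningful quadratic root in
## [0, min(S, X)].
complex_conc <- function(S, X, Kd) {
  b <- S + X + Kd
  disc <- b * b - 4 * S * X
  if (any(disc < -1e-12 * b^2)) stop("non-physical root in mass-action solve")
  C <- (b - sqrt(pmax(disc, 0))) / 2
  pmin(pmax(C, 0), pmin(S, X))
}

#' Predicted per-injection heats for the one-site (Wiseman) model
#'
#' Heat content of the cell after injection i is
#' `Q_i = V0 * dH * [complex]_i`; the observed injection heat is the
#' difference `Q_i - Q_{i-1}` plus the displaced-volume correction
#' `(v_i/V0) * (Q_i + Q_{i-1})/2` (heat carried out by the overflowed
#' liquid), plus the baseline offset. Returned in ucal.
#'
#' @param params A `one_site_params`.
#' @param protocol An `itc_protocol`.
#' @return Numeric vector of per-injection heats, ucal.
#' @export
wiseman_heats <- function(params, protocol) {
  tot <- cell_totals(protocol)
  V0 <- protocol$cell_volume
  C <- complex_conc(params$n * tot$M, tot$X, 1 / params$Ka)
  Q <- V0 * params$dH * C * 1e6          # ucal
  Qprev <- c(0, Q[-length(Q)])
  dv <- protocol$injection_volumes / V0
  Q - Qprev + dv * (Q + Qprev) / 2 + params$baseline
}

#' Simulate a noisy titration experiment
#'
#' Forward-models [wiseman_heats()] and adds iid Gaussian noise.
#'
#' @param params A `one_site_params`.
#' @param protocol An `itc_protocol`.
#' @param noise_sd Heat noise SD, ucal (>= 0).
#' @param seed Integer seed (reproducible per seed).
#' @return List of class `titration_experiment`: the protocol fields plus
#'   `heats` (ucal) and the generating `params`.
#' @export
simulate_titration <- function(params, protocol = itc_protocol(),
                               noise_sd = 0.2, seed = 1L) {
  stopifnot(noise_sd >= 0)
  mu <- wiseman_heats(params, protocol)
  heats <- withr::with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  structure(c(unclass(protocol),
              list(heats = heats, true_params = params, noise_sd = noise_sd,
                   seed = seed)),
            class = "titration_experiment")
}

#' Build a titration experiment from measured heats
#'
#' @param heats Per-injection heats, ucal.
#' @param protocol An `itc_protocol`; its injection count must match.
#' @return A `titration_experiment`.
#' @export
titration_experiment <- function(heats, protocol = itc_protocol()) {
  if (length(heats) != length(protocol$injection_volumes))
    stop("length(heats) must equal the number of injections")
  structure(c(unclass(protocol), list(heats = heats)),
            class = "titration_experiment")
}

#' Read a titration from CSV
#'
#' Expected columns: `injection_index`, `volume_ul`, `heat_ucal`.
#'
#' @param path CSV path.
#' @param cell_conc,syringe_conc,cell_volume,temperature Protocol fields
#'   (not stored in the CSV).
#' @return A `titration_experiment`.
#' @export
read_titration_csv <- function(path, cell_conc = 20e-6,
                               syringe_conc = 200e-6,
                               cell_volume = 1.43e-3,
                               temperature = 298.15) {
  d <- utils::read.csv(path)
  need <- c("injection_index", "volume_ul", "heat_ucal")
  if (!all(need %in% names(d)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$injection_index), ]
  proto <- itc_protocol(cell_conc, syringe_conc, cell_volume,
                        n_injections = nrow(d),
                        injection_volume = d$volume_ul * 1e-6,
                        temperature = temperature)
  titration_experiment(d$heat_ucal, proto)
}

#' Write a titration to CSV
#'
#' @param exp A `titration_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(exp, path) {
  utils::write.csv(data.frame(
    injection_index = seq_along(exp$heats),
    volume_ul = exp$injection_volumes * 1e6,
    heat_ucal = exp$heats
  ), path, row.names = FALSE)
  invisible(path)
}

#' Fit the one-site binding model to a titration
#'
#' Nonlinear least squares over (n, log Ka, dH, baseline), optimised in
#' log-Ka space for conditioning. Standard errors come from the local
#' curvature (Gauss-Newton covariance `s^2 (J'J)^{-1}` via the numerical
#' Hessian of the sum of squares). Fits with a Wiseman c-value
#' (`n * Ka * cell_conc`) outside [1, 1000] are flagged low-confidence.
#'
#' @param exp A `titration_experiment` with >= 6 injections.
#' @param init Optional `one_site_params` starting point; by default n = 1,
#'   Kd from a molar-ratio midpoint heuristic and dH from the first
#'   injection heat.
#' @return List of class `one_site_fit`: `params` (a `one_site_params`),
#'   `se` (named SEs for n, Kd, dH, baseline), `residual_rms` (ucal),
#'   `c_value`, `low_confidence`, `converged`, `fitted` (predicted heats).
#' @export
fit_one_site <- function(exp, init = NULL) {
  heats <- exp$heats
  if (length(heats) < 6) stop("need >= 6 injections to fit")
  proto <- itc_protocol(exp$cell_conc, exp$syringe_conc, exp$cell_volume,
                        n_injections = length(heats),
                        injection_volume = exp$injection_volumes,
                        temperature = exp$temperature)
  if (is.null(init)) init <- default_init(heats, proto)
  th0 <- c(n = init$n, logKa = log(init$Ka), dH = init$dH,
           baseline = init$baseline)
  ss <- function(th) {
    if (th[["n"]] <= 0) return(1e12)
    p <- list(n = th[["n"]], Ka = exp(th[["logKa"]]), dH = th[["dH"]],
              baseline = th[["baseline"]])
    mu <- tryCatch(wiseman_heats(p, proto), error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu))) return(1e12)
    sum((heats - mu)^2)
  }
  sc <- c(0.1, 0.5, max(abs(th0[["dH"]]), 100), max(abs(heats), 1e-9) / 10)
  opt <- stats::optim(th0, ss, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12,
                                     parscale = sc))
  opt <- stats::optim(opt$par, ss, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-12,
                                     parscale = sc))
  th <- opt$par
  if (opt$convergence != 0) {
    cond <- structure(class = c("ank_itc_nonconvergence", "error", "condition"),
                      list(message = paste0("one-site fit did not converge (code ",
                                            opt$convergence, ", SS ",
                                            signif(opt$value, 6), ")"),
                           call = sys.call(-1), best = th,
                           residual_ss = opt$value))
    stop(cond)
  }
  params <- one_site_params(n = th[["n"]], Kd = exp(-th[["logKa"]]),
                            dH = th[["dH"]], baseline = th[["baseline"]])
  fitted <- wiseman_heats(params, proto)
  dof <- max(length(heats) - 4, 1)
  s2 <- opt$value / dof
  H <- stats::optimHess(th, ss, control = list(parscale = sc))
  cov <- tryCatch(2 * s2 * solve(H), error = function(e)
    matrix(NA_real_, 4, 4))
  se_th <- unname(sqrt(pmax(diag(cov), 0)))
  ## delta method: Kd = exp(-logKa)
  se <- c(n = se_th[1], Kd = se_th[2] * params$Kd, dH = se_th[3],
          baseline = se_th[4])
  c_value <- params$n * params$Ka * exp$cell_conc
  structure(list(params = params, se = se,
                 residual_rms = sqrt(mean((heats - fitted)^2)),
                 c_value = c_value,
                 low_confidence = (c_value < 1 || c_value > 1000),
                 converged = TRUE, fitted = fitted),
            class = "one_site_fit")
}

default_init <- function(heats, proto) {
  tot <- cell_totals(proto)
  ## moles injected per shot approximates the saturable signal scale
  mol1 <- proto$syringe_conc * proto$injection_volumes[1]
  dH0 <- (heats[1] - stats::median(utils::tail(heats, 3))) * 1e-6 / mol1
  if (!is.finite(dH0) || abs(dH0) < 10) dH0 <- -5000
  ## molar-ratio midpoint: injection where cumulative signal crosses half its
  ## final value; Kd of the order of the free binder there
  base0 <- stats::median(utils::tail(heats, 3))
  cum <- cumsum(heats - base0)
  half <- which(abs(cum) >= abs(cum[length(cum)]) / 2)[1]
  Kd0 <- proto$cell_conc / 5
  if (!is.na(half)) {
    ratio <- tot$X[half] / (tot$M[half])
    Kd0 <- max(proto$cell_conc * max(0.05, abs(ratio - 1)), 1e-9)
  }
  one_site_params(n = 1, Kd = Kd0, dH = dH0, baseline = base0)
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("<one_site_fit> n=%.3f  Kd=%.3g M (+/- %.2g)  dH=%.0f cal/mol  c=%.1f%s\n",
              x$params$n, x$params$Kd, x$se[["Kd"]], x$params$dH, x$c_value,
              if (x$low_confidence) "  [low confidence: c outside 1-1000]" else ""))
  invisible(x)
}

#' Kd fold-change of a variant relative to a reference
#'
#' Values greater than 1 mean weakened binding.
#'
#' @param kd_variant,kd_reference Dissociation constants, same units, > 0.
#' @return `kd_variant / kd_reference`.
#' @export
fold_change <- function(kd_variant, kd_reference) {
  if (any(kd_variant <= 0) || any(kd_reference <= 0))
    stop("dissociation constants must be positive")
  kd_variant / kd_reference
}
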