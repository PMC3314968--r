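#' ITC titration protocol
#'
#' Describes a calorimetric titration: species in the cell at `cell_conc`
#' uM in an active volume `v0` uL, titrated by a schedule of syringe
#' injections at `syringe_conc` uM. The default schedule (38 x 1 uL into
#' 200 uL) mirrors a standard low-volume instrument run.
#'
#' @param cell_conc cell species concentration, uM.
#' @param syringe_conc syringe species concentration, uM.
#' @param v0 cell active volume, uL (default 200).
#' @param injections injection volumes, uL (default `rep(1, 38)`).
#' @param temperature Kelvin (default 298.15).
#' @param cell_species,syringe_species labels for reporting.
#' @return Object of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_conc, syringe_conc, v0 = 200,
                         injections = rep(1, 38), temperature = 298.15,
                         cell_species = "protein",
                         syringe_species = "ligand") {
  stopifnot(cell_conc > 0, syringe_conc > 0, v0 > 0,
            length(injections) > 0, all(injections > 0))
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 v0 = v0, injections = as.numeric(injections),
                 temperature = temperature, cell_species = cell_species,
                 syringe_species = syringe_species),
            class = "itc_protocol")
}

#' Single-site binding parameters
#'
#' Container for the parameters of a single set of independent sites:
#' stoichiometry `n`, dissociation constant `kd` (uM), molar enthalpy `dh`
#' (cal/mol) and a per-injection baseline `offset` (ucal). Used both as the
#' ground truth for [simulate_itc] and as the result of [fit_itc].
#'
#' @param n sites per cell-species molecule (> 0).
#' @param kd dissociation constant, uM (> 0).
#' @param dh binding enthalpy, cal/mol.
#' @param offset baseline heat per injection, ucal.
#' @return Object of class `single_site_fit`.
#' @export
single_site_fit <- function(n, kd, dh, offset = 0) {
  stopifnot(n > 0, kd > 0, is.finite(dh))
  structure(list(n = n, kd = kd, dh = dh, offset = offset,
                 se = NULL, converged = NA, flagged = FALSE, rss = NA_real_),
            class = "single_site_fit")
}

#' @export
print.single_site_fit <- function(x, ...) {
  cat(sprintf("single-site fit: n = %.3f, Kd = %.3g uM, dH = %.4g cal/mol, offset = %.3g ucal\n",
              x$n, x$kd, x$dh, x$offset))
  if (!is.null(x$se))
    cat(sprintf("  se: n %.3g, Kd %.3g, dH %.3g, offset %.3g; rss = %.4g%s\n",
                x$se["n"], x$se["kd"], x$se["dh"], x$se["offset"], x$rss,
                if (isTRUE(x$flagged)) " [FLAGGED]" else ""))
  invisible(x)
}

#' Fraction of sites occupied under single-site mass action
#'
#' Closed-form root of the binding quadratic:
#' `fb = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)`,
#' evaluated in the numerically stable form `2L / (s + sqrt(s^2 - 4PL))`.
#'
#' @param p_total total site concentration, uM (> 0).
#' @param l_total total ligand concentration, uM (>= 0, vectorised).
#' @param kd dissociation constant, uM (> 0).
#' @return Fraction bound in \[0, 1\], same length as `l_total`.
#' @export
fraction_bound <- function(p_total, l_total, kd) {
  if (any(p_total <= 0)) stop("p_total must be > 0")
  if (any(l_total < 0)) stop("l_total must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  s <- p_total + l_total + kd
  disc <- s^2 - 4 * p_total * l_total
  disc[disc < 0] <- 0  # guard rounding at stoichiometric saturation
  2 * l_total / (s + sqrt(disc))
}

## internal: noiseless injection heats (ucal) under perfusion dilution.
## After each injection of volume dv both cell species are diluted by
## (1 - dv/v0); the syringe species additionally gains dv/v0 of its stock.
## Cumulative heat Q(i) = n * Mt(i) * dH * v0 * theta(i) (ucal with uM, uL,
## cal/mol); the observed injection heat carries the displaced-volume
## correction dQ(i) = Q(i) - Q(i-1) + (dv/v0) * (Q(i) + Q(i-1)) / 2.
itc_injection_heats <- function(protocol, n, kd, dh, offset = 0) {
  dv <- protocol$injections
  v0 <- protocol$v0
  k <- length(dv)
  dil <- cumprod(1 - dv / v0)
  mt <- protocol$cell_conc * dil
  xt <- numeric(k)
  prev <- 0
  for (i in seq_len(k)) {
    xt[i] <- prev * (1 - dv[i] / v0) + protocol$syringe_conc * dv[i] / v0
    prev <- xt[i]
  }
  theta <- fraction_bound(n * mt, xt, kd)
  q <- n * mt * dh * v0 * 1e-6 * theta
  qprev <- c(0, q[-k])
  q - qprev + (dv / v0) * (q + qprev) / 2 + offset
}

#' Simulate a single-site ITC thermogram
#'
#' Generates integrated injection heats for `protocol` under single-site
#' mass action with parameters `truth`, perfusion dilution of both species,
#' the displaced-volume heat correction, and optional i.i.d. Gaussian noise.
#'
#' @param protocol an [itc_protocol].
#' @param truth a [single_site_fit] holding the generating parameters.
#' @param noise_sd Gaussian noise s.d. on each injection heat, ucal.
#' @param seed RNG seed; required whenever `noise_sd > 0`.
#' @return Data frame of class `itc_thermogram` with columns `injection`,
#'   `dv_uL`, `heat_ucal` and `ndh_kcal_mol` (heat normalised per mol of
#'   injectant); the protocol is kept in attribute `protocol`.
#' @export
simulate_itc <- function(protocol, truth, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "itc_protocol"),
            inherits(truth, "single_site_fit"), noise_sd >= 0)
  heats <- itc_injection_heats(protocol, truth$n, truth$kd, truth$dh,
                               truth$offset)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0")
    set.seed(seed)
    heats <- heats + stats::rnorm(length(heats), 0, noise_sd)
  }
  dv <- protocol$injections
  out <- data.frame(injection = seq_along(dv), dv_uL = dv,
                    heat_ucal = heats,
                    ndh_kcal_mol = heats / (protocol$syringe_conc * dv) * 1e3)
  attr(out, "protocol") <- protocol
  class(out) <- c("itc_thermogram", "data.frame")
  out
}

#' Fit a single set of independent sites to a thermogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) over (n, Kd, dH, offset),
#' with n and Kd parameterised on the log scale to keep them positive.
#' Standard errors come from the Jacobian at the optimum. A Wiseman
#' c-parameter `c = n * cell_conc / Kd` outside \[1, 1000\] triggers a
#' warning (the fit is still attempted); non-convergence or a Kd at the
#' search bound flags the fit.
#'
#' @param thermogram an `itc_thermogram` (simulated or read from disk).
#' @param protocol the matching [itc_protocol]; defaults to the protocol
#'   attached to the thermogram.
#' @param discard_first drop injection 1 before fitting (common practice
#'   for the first-injection artifact; default FALSE).
#' @return A [single_site_fit] with standard errors, `converged`, `flagged`
#'   and `rss` filled in.
#' @export
fit_itc <- function(thermogram, protocol = attr(thermogram, "protocol"),
                    discard_first = FALSE) {
  stopifnot(inherits(protocol, "itc_protocol"))
  heats <- thermogram$heat_ucal
  if (length(heats) != length(protocol$injections))
    stop("thermogram and protocol injection counts differ")
  if (length(heats) < 6) stop("need at least 6 injections to fit")
  keep <- if (discard_first) -1L else seq_along(heats)
  m0 <- protocol$cell_conc
  total_cap <- m0 * protocol$v0 * 1e-6  # umol-scale factor for dH guess
  dh0 <- sum(heats) / (0.8 * total_cap)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1000
  par0 <- c(log_n = 0, log_kd = log(m0), dh = dh0, offset = 0)
  resid_fun <- function(par) {
    model <- itc_injection_heats(protocol, exp(par[1]), exp(par[2]),
                                 par[3], par[4])
    (heats - model)[keep]
  }
  fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300, ftol = 1e-12, ptol = 1e-12))
  par <- unname(unlist(fit$par))
  out <- single_site_fit(exp(par[1]), exp(par[2]), par[3], par[4])
  out$converged <- fit$info %in% 1:4
  out$rss <- sum(fit$fvec^2)
  out$flagged <- !out$converged || out$kd < 1e-3 || out$kd > 1e7
  se <- rep(NA_real_, 4)
  cov <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(cov)) {
    se <- sqrt(pmax(diag(cov), 0))
    se[1] <- se[1] * out$n     # delta method, log scale
    se[2] <- se[2] * out$kd
  }
  names(se) <- c("n", "kd", "dh", "offset")
  out$se <- se
  cpar <- out$n * m0 / out$kd
  if (is.finite(cpar) && (cpar < 1 || cpar > 1000))
    warning(sprintf("Wiseman c = %.3g outside [1, 1000]; Kd may be poorly determined",
                    cpar))
  out
}

#' Read an ITC thermogram from TSV
#'
#' Expects columns `injection  dv_uL  heat_ucal` (comment lines `#`).
#'
#' @param path path to the table.
#' @param protocol optional [itc_protocol] to attach.
#' @return An `itc_thermogram` data frame.
#' @export
read_itc_thermogram <- function(path, protocol = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#")
  need <- c("injection", "dv_uL", "heat_ucal")
  if (!all(need %in% names(d)))
    stop("thermogram table must have columns: ", paste(need, collapse = " "))
  if (!is.null(protocol)) {
    d$ndh_kcal_mol <- d$heat_ucal / (protocol$syringe_conc * d$dv_uL) * 1e3
    attr(d, "protocol") <- protocol
  }
  class(d) <- c("itc_thermogram", "data.frame")
  d
}

#' Write an ITC thermogram as TSV
#'
#' @param thermogram an `itc_thermogram`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_itc_thermogram <- function(thermogram, path) {
  out <- data.frame(injection = thermogram$injection,
                    dv_uL = sprintf("%.4f", thermogram$dv_uL),
                    heat_ucal = sprintf("%.6f", thermogram$heat_ucal))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
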