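#' PRE prediction parameters
#'
#' Physical parameters for predicting amide intensity attenuation caused by
#' a nitroxide spin label. Defaults: rotational correlation time 10 ns,
#' diamagnetic transverse rate 20 s^-1, total transverse evolution time
#' 10 ms, 700 MHz proton frequency, and the standard nitroxide
#' electron-proton dipolar constant K = 1.23e-32 cm^6 s^-2 expressed in
#' Angstrom units (1.23e16 A^6 s^-2).
#'
#' @param tau_c rotational correlation time, s.
#' @param r2_dia diamagnetic R2, s^-1.
#' @param t_total total transverse evolution time, s.
#' @param field_mhz spectrometer 1H frequency, MHz.
#' @param k_sb dipolar constant, A^6 s^-2. Set to 0 to model the
#'   ascorbic-acid-reduced (inactivated) probe.
#' @return List of class `pre_params`.
#' @export
pre_params <- function(tau_c = 1e-8, r2_dia = 20, t_total = 0.01,
                       field_mhz = 700, k_sb = 1.23e16) {
  stopifnot(tau_c > 0, r2_dia > 0, t_total > 0, field_mhz > 0, k_sb >= 0)
  structure(list(tau_c = tau_c, r2_dia = r2_dia, t_total = t_total,
                 field_mhz = field_mhz, k_sb = k_sb),
            class = "pre_params")
}

#' Attach a pseudo spin label to a docked ubiquitin copy
#'
#' Places a single pseudo-atom representing the nitroxide at
#' `Cbeta + offset` Angstrom along the Calpha-to-Cbeta direction (default
#' offset 6 A approximates the tether of a cysteine-conjugated nitroxide;
#' no rotamer ensemble). For glycine (no Cbeta) the label is placed along
#' the local backbone normal from Calpha.
#'
#' @param model a `docked_model`.
#' @param copy placed-copy identifier: unit index or chain name (`"U1"`).
#' @param residue residue number carrying the label (ubiquitin positions
#'   6, 39, 48 and 57 correspond to the K6C/D39C/K48C/S57C probes).
#' @param offset tether length beyond Cbeta, A.
#' @return List of class `spin_label_site` with `chain`, `residue`, `xyz`.
#' @export
attach_spin_label <- function(model, copy, residue, offset = 6.0) {
  stopifnot(inherits(model, "docked_model"))
  chain <- if (is.numeric(copy)) paste0("U", copy) else copy
  s <- model$structure
  sub <- s$atoms[s$atoms$chain == chain & s$atoms$resno == residue, ,
                 drop = FALSE]
  if (nrow(sub) == 0)
    stop("residue ", residue, " not found in copy ", chain)
  ca <- atom_xyz(s, chain, residue, "CA", "spin-label site")
  has_cb <- "CB" %in% sub$elety
  if (has_cb) {
    cb <- atom_xyz(s, chain, residue, "CB", "spin-label site")
    dir <- cb - ca
    xyz <- cb + offset * dir / sqrt(sum(dir^2))
  } else {
    n <- atom_xyz(s, chain, residue, "N", "spin-label site (Gly)")
    cc <- atom_xyz(s, chain, residue, "C", "spin-label site (Gly)")
    nrm <- cross3(ca - n, cc - ca)
    if (sqrt(sum(nrm^2)) < 1e-8) nrm <- c(0, 0, 1)
    xyz <- ca + offset * nrm / sqrt(sum(nrm^2))
  }
  structure(list(chain = chain, residue = as.integer(residue),
                 xyz = as.numeric(xyz)),
            class = "spin_label_site")
}

## internal: cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## internal: amide proton positions for the receptor chains of a model.
## Uses the H atom when present; otherwise reconstructs it 1.02 A from N
## along the direction bisecting N->CA(i) and N->C(i-1); the first residue
## of a chain falls back to the N position.
receptor_amides <- function(model) {
  s <- model$structure
  out <- list()
  for (ch in model$receptor_chains) {
    a <- s$atoms[s$atoms$chain == ch, , drop = FALSE]
    res <- unique(a$resno)
    for (r in res) {
      sub <- a[a$resno == r, , drop = FALSE]
      if (!("N" %in% sub$elety)) next
      n <- as.numeric(sub[sub$elety == "N", c("x", "y", "z")][1, ])
      if ("H" %in% sub$elety) {
        h <- as.numeric(sub[sub$elety == "H", c("x", "y", "z")][1, ])
      } else {
        prev <- a[a$resno == r - 1 & a$elety == "C", , drop = FALSE]
        this_ca <- sub[sub$elety == "CA", , drop = FALSE]
        if (nrow(prev) == 1 && nrow(this_ca) >= 1) {
          cprev <- as.numeric(prev[1, c("x", "y", "z")])
          ca <- as.numeric(this_ca[1, c("x", "y", "z")])
          u1 <- n - ca; u1 <- u1 / sqrt(sum(u1^2))
          u2 <- n - cprev; u2 <- u2 / sqrt(sum(u2^2))
          d <- u1 + u2
          nd <- sqrt(sum(d^2))
          h <- if (nd > 1e-8) n + 1.02 * d / nd else n
        } else h <- n
      }
      out[[length(out) + 1L]] <- data.frame(chain = ch, residue = r,
                                            hx = h[1], hy = h[2], hz = h[3],
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Predict PRE attenuation of receptor amides from a spin-label site
#'
#' The paramagnetic rate for an amide at distance r from the label is
#' `Gamma2 = K * r^-6 * (4 tau_c + 3 tau_c / (1 + (omega_H tau_c)^2))` and
#' the predicted paramagnetic/diamagnetic intensity ratio is
#' `ratio = R2 * exp(-Gamma2 * t) / (R2 + Gamma2)`, strictly increasing
#' with distance. A coincident label (r = 0) gives ratio 0.
#'
#' @param model a `docked_model`.
#' @param site a [spin_label_site].
#' @param params a [pre_params].
#' @return Data frame of class `pre_prediction` with columns `residue`,
#'   `ratio` and `distance` (A) for every receptor amide; parameters kept
#'   in attribute `params`.
#' @export
predict_attenuation <- function(model, site, params = pre_params()) {
  stopifnot(inherits(model, "docked_model"),
            inherits(site, "spin_label_site"),
            inherits(params, "pre_params"))
  am <- receptor_amides(model)
  if (is.null(am) || nrow(am) == 0) stop("no receptor amides resolvable")
  r <- sqrt((am$hx - site$xyz[1])^2 + (am$hy - site$xyz[2])^2 +
              (am$hz - site$xyz[3])^2)
  omega <- 2 * pi * params$field_mhz * 1e6
  j <- 4 * params$tau_c + 3 * params$tau_c / (1 + (omega * params$tau_c)^2)
  gamma2 <- ifelse(r > 0, params$k_sb * r^-6 * j, Inf)
  ratio <- ifelse(is.finite(gamma2),
                  params$r2_dia * exp(-gamma2 * params$t_total) /
                    (params$r2_dia + gamma2),
                  0)
  out <- data.frame(residue = am$residue, ratio = ratio, distance = r)
  attr(out, "params") <- params
  attr(out, "site") <- site
  class(out) <- c("pre_prediction", "data.frame")
  out
}

#' Significant attenuation regions of a PRE profile
#'
#' Contiguous runs of at least `min_run` residues whose intensity ratio
#' falls below `threshold` (defaults 0.7 and 2; flagged residues ignored).
#'
#' @param profile a `pre_prediction` or observed `pre_profile` (columns
#'   `residue`, `ratio`, optional `flagged`).
#' @param threshold ratio below which a residue counts as attenuated.
#' @param min_run minimum region length in residues.
#' @return Data frame with columns `start`, `end`, `n_residues`.
#' @export
significant_regions <- function(profile, threshold = 0.7, min_run = 2) {
  if (threshold <= 0 || min_run < 1) stop("invalid thresholds")
  flagged <- if ("flagged" %in% names(profile)) profile$flagged else FALSE
  hit <- profile$residue[profile$ratio < threshold & !flagged]
  reg <- contiguous_regions(hit, max_gap = 0)
  if (nrow(reg) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_residues = integer()))
  reg$n_residues <- vapply(seq_len(nrow(reg)), function(i)
    sum(hit >= reg$start[i] & hit <= reg$end[i]), integer(1))
  reg[reg$n_residues >= min_run, , drop = FALSE]
}

#' Compare observed and predicted PRE profiles
#'
#' Per-residue residuals (observed - predicted) over shared residues, plus
#' a region-agreement score: the Jaccard index of the residue sets covered
#' by the significant-attenuation regions of each profile (1 when both
#' profiles have no significant region).
#'
#' @param observed data frame with columns `residue`, `ratio` (and optional
#'   `flagged`).
#' @param predicted a `pre_prediction`.
#' @param threshold,min_run region-call settings passed to
#'   [significant_regions].
#' @return List of class `pre_comparison` with `residuals` (data frame)
#'   and `jaccard`.
#' @export
compare_pre <- function(observed, predicted, threshold = 0.7, min_run = 2) {
  shared <- intersect(observed$residue, predicted$residue)
  if (length(shared) < 10)
    stop("fewer than 10 shared residues between observed and predicted")
  obs <- observed[match(shared, observed$residue), , drop = FALSE]
  prd <- predicted[match(shared, predicted$residue), , drop = FALSE]
  resid <- data.frame(residue = shared,
                      observed = obs$ratio, predicted = prd$ratio,
                      residual = obs$ratio - prd$ratio)
  region_set <- function(p) {
    reg <- significant_regions(p, threshold, min_run)
    if (nrow(reg) == 0) return(integer(0))
    unlist(lapply(seq_len(nrow(reg)), function(i) reg$start[i]:reg$end[i]))
  }
  so <- region_set(obs); sp <- region_set(prd)
  jac <- if (length(so) == 0 && length(sp) == 0) 1 else
    length(intersect(so, sp)) / length(union(so, sp))
  structure(list(residuals = resid, jaccard = jac), class = "pre_comparison")
}

#' @export
print.pre_comparison <- function(x, ...) {
  cat(sprintf("PRE comparison: %d residues, rms residual %.4f, region Jaccard %.3f\n",
              nrow(x$residuals), sqrt(mean(x$residuals$residual^2)), x$jaccard))
  invisible(x)
}

#' Read an observed PRE profile from TSV
#'
#' Expects columns `residue  I_ratio` (comment lines `#`). Ratios must be
#' non-negative; missing residues are simply absent from the table.
#'
#' @param path path to the table.
#' @return Data frame of class `pre_profile` with columns `residue`,
#'   `ratio`.
#' @export
read_pre_profile <- function(path) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (!all(c("residue", "I_ratio") %in% names(d)))
    stop("PRE table must have columns: residue I_ratio")
  if (any(d$I_ratio < 0)) stop("intensity ratios must be >= 0")
  out <- data.frame(residue = as.integer(d$residue), ratio = d$I_ratio)
  class(out) <- c("pre_profile", "data.frame")
  out
}
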