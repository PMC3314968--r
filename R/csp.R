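#' Amide peak list
#'
#' One backbone amide (1H, 15N) resonance per residue, as observed in an
#' HSQC spectrum of an assigned protein. Shifts far outside typical amide
#' ranges (1H 5-12 ppm, 15N 100-135 ppm) trigger a warning, not an error.
#'
#' @param residue integer residue numbers (unique).
#' @param dH,dN proton and nitrogen chemical shifts, ppm.
#' @param label state label, e.g. `"apo"` or `"2 eq"`.
#' @return Data frame of class `peak_list` with columns `residue`, `dH`,
#'   `dN`, ordered by residue; the label is kept in attribute `label`.
#' @export
peak_list <- function(residue, dH, dN, label = "") {
  residue <- as.integer(residue)
  if (anyDuplicated(residue))
    stop("duplicate residue in peak list: ",
         residue[duplicated(residue)][1])
  if (!all(is.finite(dH)) || !all(is.finite(dN)))
    stop("non-finite chemical shift")
  if (any(dH < 5 | dH > 12) || any(dN < 100 | dN > 135))
    warning("chemical shifts outside typical amide ranges ",
            "(1H 5-12 ppm, 15N 100-135 ppm)")
  out <- data.frame(residue = residue, dH = dH, dN = dN)
  out <- out[order(out$residue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Read a peak list from a whitespace/TSV table
#'
#' Expects columns `residue dH_ppm dN_ppm`; lines starting with `#` are
#' comments. The residue column may be numeric or a Sparky-style assignment
#' string such as `T44N-H`, from which the residue number is extracted.
#'
#' @param path path to the table.
#' @param label state label stored on the result.
#' @return A [peak_list].
#' @export
read_peaklist <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no data rows in ", path)
  res <- integer(0); dh <- numeric(0); dn <- numeric(0)
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 3)
      stop("line ", i, ": expected 3 columns (residue dH dN), got ",
           length(f))
    r <- suppressWarnings(as.numeric(f[1]))
    if (is.na(r)) {  # Sparky-style assignment label, e.g. "T44N-H"
      num <- regmatches(f[1], regexpr("[0-9]+", f[1]))
      if (length(num) == 0)
        stop("line ", i, ": cannot parse residue from '", f[1], "'")
      r <- as.numeric(num)
    }
    h <- suppressWarnings(as.numeric(f[2]))
    n <- suppressWarnings(as.numeric(f[3]))
    if (is.na(h) || is.na(n))
      stop("line ", i, ": non-numeric chemical shift")
    res <- c(res, as.integer(r)); dh <- c(dh, h); dn <- c(dn, n)
  }
  if (anyDuplicated(res))
    stop("duplicate residue ", res[duplicated(res)][1], " in ", path)
  peak_list(res, dh, dn, label = label)
}

#' Write a peak list as a whitespace table
#'
#' Emits the dialect read by [read_peaklist]: a `#` header followed by
#' `residue dH_ppm dN_ppm` rows (shifts to 4 decimals).
#'
#' @param peaks a [peak_list].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_peaklist <- function(peaks, path) {
  lines <- c("# residue dH_ppm dN_ppm",
             sprintf("%d\t%.4f\t%.4f", peaks$residue, peaks$dH, peaks$dN))
  writeLines(lines, path)
  invisible(path)
}

#' Chemical shift perturbation between two states
#'
#' Per-residue amide CSP with the 15N shift down-weighted by 5:
#' `csp = sqrt(dH_delta^2 + (dN_delta/5)^2)`. Residues present in only one
#' list (e.g. prolines, which have no amide peak) or listed in `exclude`
#' are assigned 0 ppm and flagged; flagged residues are ignored by interface
#' mapping and titration fitting.
#'
#' @param apo,bound [peak_list] objects for the reference and perturbed
#'   states.
#' @param exclude residues to force-flag (e.g. prolines).
#' @return Data frame of class `csp_profile` with columns `residue`,
#'   `csp` (ppm, >= 0) and `flagged`.
#' @export
compute_csp <- function(apo, bound, exclude = integer(0)) {
  shared <- intersect(apo$residue, bound$residue)
  if (length(shared) == 0) stop("peak lists share no residues")
  all_res <- sort(union(apo$residue, bound$residue))
  csp <- numeric(length(all_res))
  flagged <- !(all_res %in% shared) | all_res %in% exclude
  i <- match(shared, all_res)
  dh <- bound$dH[match(shared, bound$residue)] -
    apo$dH[match(shared, apo$residue)]
  dn <- bound$dN[match(shared, bound$residue)] -
    apo$dN[match(shared, apo$residue)]
  csp[i] <- sqrt(dh^2 + (dn / 5)^2)
  csp[flagged] <- 0
  out <- data.frame(residue = all_res, csp = csp, flagged = flagged)
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Interface residues from a CSP profile
#'
#' @param profile a `csp_profile` from [compute_csp].
#' @param threshold CSP cutoff in ppm (default 0.2, the operative interface
#'   cutoff for UBA/ubiquitin mapping); residues with `csp > threshold` and
#'   not flagged are reported.
#' @return Integer vector of residue numbers.
#' @export
map_interface_residues <- function(profile, threshold = 0.2) {
  if (threshold <= 0) stop("threshold must be > 0")
  profile$residue[profile$csp > threshold & !profile$flagged]
}

#' Contiguous residue regions
#'
#' Collapses a set of residue numbers into maximal runs in which successive
#' members differ by at most `max_gap + 1`.
#'
#' @param residues integer residue numbers (ascending).
#' @param max_gap largest tolerated gap inside a region (default 0 =
#'   strictly consecutive).
#' @return Data frame with columns `start`, `end`.
#' @export
contiguous_regions <- function(residues, max_gap = 0) {
  if (length(residues) == 0)
    return(data.frame(start = integer(), end = integer()))
  residues <- sort(unique(as.integer(residues)))
  brk <- which(diff(residues) > max_gap + 1)
  start <- residues[c(1, brk + 1)]
  end <- residues[c(brk, length(residues))]
  data.frame(start = start, end = end)
}

#' Titration series
#'
#' An ordered set of peak lists recorded at increasing total ligand
#' concentration, starting from the apo state, at fixed labelled-protein
#' concentration (fast-exchange regime: peaks move continuously with
#' fraction bound).
#'
#' @param p_total labelled-protein concentration, uM.
#' @param ligand total ligand concentrations, uM, strictly increasing from 0.
#' @param peaklists list of [peak_list] objects, one per ligand point.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(p_total, ligand, peaklists) {
  stopifnot(p_total > 0, length(ligand) == length(peaklists))
  if (ligand[1] != 0) stop("first titration point must be apo (0 uM)")
  if (any(diff(ligand) <= 0))
    stop("ligand concentrations must be strictly increasing")
  structure(list(p_total = p_total, ligand = as.numeric(ligand),
                 peaklists = peaklists),
            class = "titration_series")
}

#' Fit a shared Kd to a fast-exchange titration
#'
#' Models the observed CSP of each responsive residue as
#' `csp(r, L) = dmax_r * fb(P, L, Kd)` with `fb` the single-site quadratic
#' fraction bound ([fraction_bound]) and one global Kd. For a given Kd the
#' per-residue amplitudes have a closed-form least-squares solution, so the
#' fit reduces to a 1-D minimisation over log Kd (coarse grid followed by
#' golden-section refinement).
#'
#' @param series a [titration_series].
#' @param min_response smallest maximal CSP (ppm) for a residue to count as
#'   responsive (default 0.05, a few times the per-point noise
#'   of a typical titration).
#' @param kd_range search range for Kd, uM.
#' @return List of class `titration_fit` with `kd` (uM), `dmax` (named
#'   per-residue amplitudes, ppm), `rss`, `residues`, `n_points`.
#' @export
fit_titration_kd <- function(series, min_response = 0.05,
                             kd_range = c(0.1, 1e5)) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$ligand) < 3) stop("need at least 3 titration points")
  apo <- series$peaklists[[1]]
  profs <- lapply(series$peaklists[-1], function(p) compute_csp(apo, p))
  res <- sort(Reduce(intersect, lapply(profs, function(p)
    p$residue[!p$flagged])))
  D <- vapply(profs, function(p) p$csp[match(res, p$residue)],
              numeric(length(res)))
  D <- matrix(D, nrow = length(res))
  responsive <- apply(D, 1, max) > min_response
  if (!any(responsive))
    stop("no responsive residues (all CSPs below ", min_response, " ppm)")
  D <- D[responsive, , drop = FALSE]
  res <- res[responsive]
  L <- series$ligand[-1]
  rss_of <- function(log10kd) {
    fb <- fraction_bound(series$p_total, L, 10^log10kd)
    dmax <- as.numeric(D %*% fb) / sum(fb^2)
    sum((D - outer(dmax, fb))^2)
  }
  grid <- seq(log10(kd_range[1]), log10(kd_range[2]), length.out = 81)
  vals <- vapply(grid, rss_of, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(rss_of, c(lo, hi), tol = 1e-10)
  kd <- 10^opt$minimum
  if (kd <= 1.001 * kd_range[1] || kd >= 0.999 * kd_range[2])
    warning("fitted Kd at search bound; fit may be unreliable")
  fb <- fraction_bound(series$p_total, L, kd)
  dmax <- as.numeric(D %*% fb) / sum(fb^2)
  names(dmax) <- res
  structure(list(kd = kd, dmax = dmax, rss = opt$objective,
                 residues = res, n_points = length(L)),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("fast-exchange titration fit: Kd = %.3g uM, %d residues, rss = %.3g\n",
              x$kd, length(x$residues), x$rss))
  invisible(x)
}

#' Export a CSP profile as TSV
#'
#' Writes columns `residue  csp_ppm  flag`.
#'
#' @param profile a `csp_profile`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_csp_profile <- function(profile, path) {
  out <- data.frame(residue = profile$residue,
                    csp_ppm = sprintf("%.6f", profile$csp),
                    flag = as.integer(profile$flagged))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-residue CSPs into the B-factor column of a structure
#'
#' @param s a [structure3d].
#' @param profile a `csp_profile`.
#' @param chain chain to annotate (default: first chain).
#' @return The annotated [structure3d].
#' @export
annotate_bfactor_csp <- function(s, profile, chain = NULL) {
  stopifnot(inherits(s, "structure3d"))
  if (is.null(chain)) chain <- s$atoms$chain[1]
  i <- s$atoms$chain == chain
  v <- profile$csp[match(s$atoms$resno[i], profile$residue)]
  v[is.na(v)] <- 0
  s$atoms$b[i] <- round(v, 2)
  s
}
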