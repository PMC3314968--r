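#' Specification for a synthetic overlapping-UBA solenoid
#'
#' Describes an idealised right-handed solenoid of alpha-helices: helix k
#' is generated from helix k-1 by a fixed screw motion (rotation by `twist`
#' degrees about the solenoid axis plus a `rise` Angstrom translation), so
#' every three-helix UBA unit is congruent with every other. The default
#' seven-helix geometry yields three overlapping UBA units.
#'
#' @param seed RNG seed for the small coordinate jitter (mandatory).
#' @param n_helices odd helix count >= 3 (default 7).
#' @param helix_len residues per helix (default 11).
#' @param loop_len residues per inter-helix loop (default 3).
#' @param radius superhelical radius, A (default 14).
#' @param rise axial rise per helix, A (default 9).
#' @param twist rotation per helix about the solenoid axis, degrees
#'   (default 40; positive = right-handed).
#' @param tilt helix-axis tilt from the solenoid axis, degrees (default 15).
#' @param jitter s.d. of Gaussian coordinate jitter, A (default 0.05).
#' @return List of class `solenoid_spec`.
#' @export
solenoid_spec <- function(seed, n_helices = 7, helix_len = 11, loop_len = 3,
                          radius = 14, rise = 9, twist = 40, tilt = 15,
                          jitter = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_helices < 3 || n_helices %% 2 == 0)
    stop("n_helices must be odd and >= 3, got ", n_helices)
  stopifnot(helix_len >= 6, loop_len >= 0, radius > 0, rise > 0,
            jitter >= 0)
  structure(list(seed = as.integer(seed), n_helices = as.integer(n_helices),
                 helix_len = as.integer(helix_len),
                 loop_len = as.integer(loop_len), radius = radius,
                 rise = rise, twist = twist, tilt = tilt, jitter = jitter),
            class = "solenoid_spec")
}

## internal rotation matrices
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
         byrow = TRUE)
}

## internal: Calpha trace of an ideal alpha-helix along +z or -z,
## centred at the origin (2.3 A radius, 1.5 A rise, 100 deg per residue)
ideal_helix_ca <- function(n, up = TRUE) {
  j <- seq_len(n) - 1
  z <- 1.5 * (j - (n - 1) / 2) * if (up) 1 else -1
  cbind(2.3 * cos(j * 100 * pi / 180), 2.3 * sin(j * 100 * pi / 180), z)
}

## internal: build N/CA/C/O/CB (+NZ for Lys) records on a Calpha trace.
## Geometry is approximate and intended for Calpha-based analysis, amide
## reconstruction and distance work, not for stereochemical realism.
## cb_dir, when given, overrides the Cbeta direction per residue (rows).
backbone_from_ca <- function(ca, resnames, chain, cb_dir = NULL) {
  n <- nrow(ca)
  stopifnot(length(resnames) == n)
  unitv <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) c(1, 0, 0) else v / nv
  }
  any_perp <- function(v) {
    p <- cross3(v, c(0, 0, 1))
    if (sqrt(sum(p^2)) < 1e-6) p <- cross3(v, c(0, 1, 0))
    unitv(p)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    u_prev <- if (i > 1) unitv(ca[i - 1, ] - ca[i, ]) else
      -unitv(ca[i + 1, ] - ca[i, ])
    u_next <- if (i < n) unitv(ca[i + 1, ] - ca[i, ]) else
      -unitv(ca[i - 1, ] - ca[i, ])
    nrm <- cross3(u_prev, u_next)
    nrm <- if (sqrt(sum(nrm^2)) < 1e-6) any_perp(u_next) else unitv(nrm)
    npos <- ca[i, ] + 1.46 * u_prev
    cpos <- ca[i, ] + 1.52 * u_next
    opos <- cpos + 1.23 * nrm
    at <- data.frame(
      chain = chain, resno = i, resid = resnames[i],
      elety = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = c(npos[1], ca[i, 1], cpos[1], opos[1]),
      y = c(npos[2], ca[i, 2], cpos[2], opos[2]),
      z = c(npos[3], ca[i, 3], cpos[3], opos[3]),
      stringsAsFactors = FALSE)
    if (resnames[i] != "GLY") {
      bdir <- if (!is.null(cb_dir)) unitv(cb_dir[i, ]) else {
        v <- -(u_prev + u_next)
        if (sqrt(sum(v^2)) < 1e-6) any_perp(u_next) else unitv(v)
      }
      cb <- ca[i, ] + 1.53 * bdir
      at <- rbind(at, data.frame(chain = chain, resno = i,
                                 resid = resnames[i], elety = "CB",
                                 element = "C", x = cb[1], y = cb[2],
                                 z = cb[3], stringsAsFactors = FALSE))
      if (resnames[i] == "LYS") {
        nz <- cb + 2.8 * bdir
        at <- rbind(at, data.frame(chain = chain, resno = i,
                                   resid = resnames[i], elety = "NZ",
                                   element = "N", x = nz[1], y = nz[2],
                                   z = nz[3], stringsAsFactors = FALSE))
      }
    }
    rows[[i]] <- at
  }
  atoms <- do.call(rbind, rows)
  atoms$o <- 1; atoms$b <- 0
  atoms
}

## internal: reject self-intersecting Calpha traces
check_self_intersection <- function(ca, min_dist = 2.5) {
  n <- nrow(ca)
  d <- cross_dist(ca, ca)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  bad <- d < min_dist & sep >= 3
  if (any(bad))
    stop("generated backbone self-intersects (Calpha pair closer than ",
         min_dist, " A); spec rejected")
  invisible(TRUE)
}

#' Generate a synthetic overlapping-UBA solenoid
#'
#' Builds ideal alpha-helices (1.5 A rise, 100 degrees per residue) on a
#' right-handed superhelical path with exact per-helix screw symmetry, adds
#' linear inter-helix loops and a small seeded coordinate jitter, and
#' returns the structure with its construction ground truth. The sequence
#' is polyalanine except that the loop following the first helix of each
#' UBA unit carries the signature motif (`MGF`, with the degenerate `KGF`
#' variant in unit 2).
#'
#' @param spec a [solenoid_spec].
#' @return List of class `solenoid_model`: `structure` (chain A),
#'   `helices` (ground-truth segments), `units` (ground-truth UBA units),
#'   `sequence`, `spec`.
#' @export
make_solenoid <- function(spec) {
  stopifnot(inherits(spec, "solenoid_spec"))
  L <- spec$helix_len; G <- spec$loop_len; H <- spec$n_helices
  period <- L + G
  n_res <- H * L + (H - 1) * G
  ca <- matrix(NA_real_, n_res, 3)
  helix_rows <- list()
  base <- ideal_helix_ca(L, up = TRUE) %*% t(rot_y(spec$tilt))
  for (k in seq_len(H)) {
    theta <- (k - 1) * spec$twist
    centre <- c(spec$radius * cos(theta * pi / 180),
                spec$radius * sin(theta * pi / 180),
                (k - 1) * spec$rise)
    hk <- base %*% t(rot_z(theta))
    hk <- sweep(hk, 2, centre, "+")
    start <- (k - 1) * period + 1L
    ca[start:(start + L - 1L), ] <- hk
    helix_rows[[k]] <- data.frame(chain = "A", start = start,
                                  end = start + L - 1L, length = L,
                                  stringsAsFactors = FALSE)
    if (k < H && G > 0) {
      p0 <- hk[L, ]
      theta2 <- k * spec$twist
      centre2 <- c(spec$radius * cos(theta2 * pi / 180),
                   spec$radius * sin(theta2 * pi / 180), k * spec$rise)
      p1 <- (base %*% t(rot_z(theta2)))[1, ] + centre2
      mid <- (p0 + p1) / 2
      out_dir <- c(mid[1], mid[2], 0)
      out_dir <- out_dir / max(sqrt(sum(out_dir^2)), 1e-9)
      for (g in seq_len(G)) {
        frac <- g / (G + 1)
        # bow the loop radially outward so it clears the helix bodies
        ca[start + L - 1L + g, ] <- p0 + frac * (p1 - p0) +
          4.0 * sin(pi * frac) * out_dir
      }
    }
  }
  set.seed(spec$seed)
  if (spec$jitter > 0)
    ca <- ca + matrix(stats::rnorm(length(ca), 0, spec$jitter), n_res, 3)
  check_self_intersection(ca)
  seq1 <- rep("A", n_res)
  n_units <- (H - 1L) / 2L
  for (i in seq_len(n_units)) {
    if (G < 3) break
    loop_start <- (2L * i - 1L) * period - G + 1L
    motif <- if (i == 2) c("K", "G", "F") else c("M", "G", "F")
    seq1[loop_start + 0:2] <- motif
  }
  resnames <- bio3d::aa123(seq1)
  atoms <- backbone_from_ca(ca, resnames, chain = "A")
  helices <- do.call(rbind, helix_rows)
  class(helices) <- c("helix_segments", "data.frame")
  units <- decompose_overlapping_ubas(helices)
  structure(list(structure = structure3d(atoms), helices = helices,
                 units = units, sequence = paste(seq1, collapse = ""),
                 spec = spec),
            class = "solenoid_model")
}

#' Generate a compact ubiquitin-like decoy domain
#'
#' A 76-residue geometric stand-in for monoubiquitin: five short ideal
#' helices packed as a two-row bundle, with the chain segments arranged so
#' that the canonical hydrophobic-patch markers (Ile44, Val70) and the
#' spin-label positions 6 and 48 sit on the front (binding) face while
#' positions 39 and 57 sit on the back face, reproducing the geometry that
#' makes K6C/K48C probes report on a bound partner and D39C/S57C silent.
#' Side-chain direction vectors point radially away from the bundle axis.
#' Named atoms required downstream are present: Lys48/Lys63 NZ, Gly76
#' carbonyl C, and Cbeta for all non-glycine residues. This is a synthetic
#' decoy, not a ubiquitin fold.
#'
#' @param seed RNG seed for the coordinate jitter (mandatory).
#' @param jitter s.d. of Gaussian coordinate jitter, A (default 0.05).
#' @return A [structure3d] (chain U, residues 1-76) with attributes
#'   `patch` (c(44, 70)) and `front_dir` (unit vector of the binding face).
#' @export
make_ub_like_domain <- function(seed, jitter = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  segs <- list(
    list(res = 1:20,  centre = c(4.5, -9), up = TRUE),
    list(res = 21:41, centre = c(-4.5, -5), up = FALSE),
    list(res = 42:52, centre = c(4.5, 0), up = TRUE),
    list(res = 53:60, centre = c(-4.5, 5), up = FALSE),
    list(res = 61:76, centre = c(4.5, 9), up = TRUE))
  ca <- matrix(NA_real_, 76, 3)
  for (sg in segs) {
    m <- length(sg$res)
    h <- ideal_helix_ca(m, up = sg$up)
    h[, 1] <- h[, 1] + sg$centre[1]
    h[, 2] <- h[, 2] + sg$centre[2]
    ca[sg$res, ] <- h
  }
  set.seed(seed)
  if (jitter > 0)
    ca <- ca + matrix(stats::rnorm(length(ca), 0, jitter), 76, 3)
  cb_dir <- t(apply(ca, 1, function(p) {
    v <- c(p[1], p[2], 0)
    n <- sqrt(sum(v^2))
    if (n < 1e-6) c(1, 0, 0) else v / n
  }))
  seq1 <- rep("A", 76)
  seq1[c(6, 48, 63)] <- "K"
  seq1[44] <- "I"; seq1[70] <- "V"; seq1[39] <- "D"; seq1[57] <- "S"
  seq1[76] <- "G"
  atoms <- backbone_from_ca(ca, bio3d::aa123(seq1), chain = "U",
                            cb_dir = cb_dir)
  out <- structure3d(atoms)
  attr(out, "patch") <- c(44L, 70L)
  attr(out, "front_dir") <- c(1, 0, 0)
  out
}

#' Generate a synthetic template UBA:ubiquitin complex
#'
#' Takes the first three helices of a default synthetic solenoid as the
#' template UBA (chain T), poses a ubiquitin-like decoy (chain U) against
#' the helix-1/helix-3 outer face with its binding face towards the UBA,
#' and slides it along the face normal until the minimum heavy-atom
#' separation is `contact_dist` (default 4.0 A: in contact, but clash-free
#' at the 2.4 A criterion). The pose is found by bisection and is fully
#' deterministic given the seed.
#'
#' @param seed RNG seed (mandatory; the decoy uses `seed + 1`).
#' @param contact_dist target minimum heavy-atom separation, A.
#' @return A [template_complex].
#' @export
make_template_complex <- function(seed, contact_dist = 4.0) {
  if (missing(seed)) stop("seed is mandatory")
  sol <- make_solenoid(solenoid_spec(seed = seed))
  keep_end <- sol$helices$end[3]
  at <- sol$structure$atoms
  at <- at[at$resno <= keep_end, , drop = FALSE]
  at$chain <- "T"
  uba <- structure3d(at)
  helices <- sol$helices[1:3, , drop = FALSE]
  helices$chain <- "T"
  class(helices) <- c("helix_segments", "data.frame")

  ub <- make_ub_like_domain(seed + 1L)
  twist <- sol$spec$twist
  u <- c(cos(twist * pi / 180), sin(twist * pi / 180), 0)
  R <- rot_z(180 + twist)  # decoy front (+x) faces -u
  ub_xyz <- as.matrix(ub$atoms[, c("x", "y", "z")]) %*% t(R)
  uba_heavy <- as.matrix(heavy_atoms(uba$atoms)[, c("x", "y", "z")])
  ub_heavy_idx <- toupper(ub$atoms$element) != "H"
  c0 <- colMeans(atom_coords(uba, elety = "CA"))
  mindist_at <- function(t) {
    shifted <- sweep(ub_xyz, 2, c0 + t * u, "+")
    min(cross_dist(shifted[ub_heavy_idx, , drop = FALSE], uba_heavy))
  }
  lo <- 0; hi <- 100
  if (mindist_at(hi) < contact_dist)
    stop("cannot pose decoy: no clash-free separation found")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (mindist_at(mid) < contact_dist) lo <- mid else hi <- mid
  }
  shifted <- sweep(ub_xyz, 2, c0 + hi * u, "+")
  ub$atoms$x <- shifted[, 1]; ub$atoms$y <- shifted[, 2]
  ub$atoms$z <- shifted[, 3]
  combined <- structure3d(rbind(uba$atoms, ub$atoms))
  tmpl <- template_complex(combined, uba_chain = "T", ub_chain = "U",
                           helices = helices)
  cl <- detect_clashes(combined, cutoff = 2.4)
  if (nrow(cl$contacts) > 0)
    stop("generated template pose has internal clashes; spec rejected")
  tmpl
}

#' Specification for a synthetic fast-exchange HSQC titration
#'
#' Defaults mirror a typical UBA/ubiquitin titration: 500 uM labelled
#' protein, ligand up to 3 molar equivalents, true Kd 70 uM, 12 perturbed
#' residues (the signature-motif loops of a default synthetic solenoid plus
#' the preceding helix-end residue) with a maximal combined CSP of 0.4 ppm,
#' and 0.01 ppm shift noise.
#'
#' @param seed RNG seed (mandatory).
#' @param p_total labelled protein concentration, uM.
#' @param equivalents ligand schedule in molar equivalents, increasing
#'   from 0.
#' @param kd true dissociation constant, uM.
#' @param n_residues protein length (residues 1..n).
#' @param perturbed residues shifted on binding.
#' @param dmax maximal combined CSP per perturbed residue, ppm (recycled).
#' @param prolines residues absent from every peak list (no amide).
#' @param noise_sd Gaussian shift noise on 1H, ppm (15N noise is 5x).
#' @return List of class `titration_spec`.
#' @export
titration_spec <- function(seed, p_total = 500,
                           equivalents = c(0, 0.1, 0.25, 0.5, 0.75, 1,
                                           1.5, 2, 2.5, 3),
                           kd = 70, n_residues = 95,
                           perturbed = c(11:14, 39:42, 67:70),
                           dmax = 0.4, prolines = c(33L, 61L),
                           noise_sd = 0.01) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(p_total > 0, kd > 0, noise_sd >= 0,
            equivalents[1] == 0, all(diff(equivalents) > 0),
            all(perturbed >= 1 & perturbed <= n_residues))
  dmax <- rep_len(dmax, length(perturbed))
  structure(list(seed = as.integer(seed), p_total = p_total,
                 equivalents = equivalents, kd = kd,
                 n_residues = as.integer(n_residues),
                 perturbed = as.integer(perturbed), dmax = dmax,
                 prolines = as.integer(prolines), noise_sd = noise_sd),
            class = "titration_spec")
}

#' Simulate a fast-exchange HSQC titration
#'
#' In fast exchange the observed peak is the population-weighted average of
#' free and bound positions, so each perturbed residue moves linearly with
#' fraction bound: `delta(L) = delta_free + fb(P, L, Kd) * delta_max`. The
#' per-residue maximal shift is split between 1H and 15N by a random phase
#' so the combined CSP at saturation equals `dmax`. Prolines are omitted
#' from every peak list.
#'
#' @param spec a [titration_spec].
#' @return A [titration_series]; the generating truth is in attribute
#'   `truth`.
#' @export
simulate_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  res <- setdiff(seq_len(n), spec$prolines)
  dh0 <- stats::runif(n, 7.5, 9.3)
  dn0 <- stats::runif(n, 106, 130)
  phi <- stats::runif(length(spec$perturbed), 0, 2 * pi)
  dh_max <- numeric(n); dn_max <- numeric(n)
  dh_max[spec$perturbed] <- spec$dmax * cos(phi)
  dn_max[spec$perturbed] <- 5 * spec$dmax * sin(phi)
  ligand <- spec$equivalents * spec$p_total
  fb <- fraction_bound(spec$p_total, ligand, spec$kd)
  lists <- lapply(seq_along(ligand), function(i) {
    dh <- dh0 + fb[i] * dh_max
    dn <- dn0 + fb[i] * dn_max
    if (spec$noise_sd > 0) {
      dh <- dh + stats::rnorm(n, 0, spec$noise_sd)
      dn <- dn + stats::rnorm(n, 0, 5 * spec$noise_sd)
    }
    label <- if (i == 1) "apo" else
      sprintf("%.2f eq", spec$equivalents[i])
    peak_list(res, dh[res], dn[res], label = label)
  })
  out <- titration_series(spec$p_total, ligand, lists)
  attr(out, "truth") <- list(kd = spec$kd, perturbed = spec$perturbed,
                             dmax = spec$dmax, prolines = spec$prolines,
                             fraction_bound = fb)
  out
}

#' Simulate an observed PRE profile from a docked model
#'
#' Predicted attenuation ratios ([predict_attenuation]) plus Gaussian
#' noise, clipped at zero — the synthetic analogue of comparing the active
#' spin label against the ascorbic-acid-reduced control.
#'
#' @param model a `docked_model`.
#' @param site a [spin_label_site].
#' @param noise_sd Gaussian noise s.d. on the intensity ratio.
#' @param seed RNG seed (mandatory when `noise_sd > 0`).
#' @param params a [pre_params].
#' @return Data frame of class `pre_profile` with columns `residue`,
#'   `ratio`; the generating prediction is in attribute `truth`.
#' @export
simulate_pre_observed <- function(model, site, noise_sd = 0.05, seed = NULL,
                                  params = pre_params()) {
  pred <- predict_attenuation(model, site, params)
  ratio <- pred$ratio
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0")
    set.seed(seed)
    ratio <- pmax(0, ratio + stats::rnorm(length(ratio), 0, noise_sd))
  }
  out <- data.frame(residue = pred$residue, ratio = ratio)
  attr(out, "truth") <- pred
  class(out) <- c("pre_profile", "data.frame")
  out
}
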