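# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: different algorithm, no shared code path.

# Quaternion characteristic-polynomial RMSD (Theobald): the optimal
# superposition RMSD from the largest eigenvalue of the 4x4 key matrix,
# no rotation matrix ever formed.
qcp_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  S <- crossprod(Ac, Bc)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(Ac^2) + sum(Bc^2) - 2 * lam) / nrow(A))
}

# Bisection solution of the single-site equilibrium Kd = (P-B)(L-B)/B for
# the bound concentration B, returned as fraction bound B/P.
bisect_fraction_bound <- function(p, l, kd) {
  if (l == 0) return(0)
  g <- function(b) (p - b) * (l - b) - kd * b
  lo <- 0; hi <- min(p, l)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 / p
}

# All-pairs inter-chain heavy-atom clash count, plain double loop.
brute_clash_count <- function(s, chain1, chain2, cutoff) {
  a <- s$atoms[toupper(s$atoms$element) != "H", ]
  a1 <- a[a$chain == chain1, ]; a2 <- a[a$chain == chain2, ]
  n <- 0L
  for (i in seq_len(nrow(a1))) for (j in seq_len(nrow(a2))) {
    d <- sqrt((a1$x[i] - a2$x[j])^2 + (a1$y[i] - a2$y[j])^2 +
                (a1$z[i] - a2$z[j])^2)
    if (d < cutoff) n <- n + 1L
  }
  n
}

# Brute-force contiguous-region finder: grow regions element by element.
brute_regions <- function(residues, max_gap) {
  residues <- sort(unique(residues))
  if (length(residues) == 0)
    return(data.frame(start = integer(), end = integer()))
  starts <- ends <- integer(0)
  cur_start <- cur_end <- residues[1]
  for (r in residues[-1]) {
    if (r - cur_end <= max_gap + 1) cur_end <- r
    else {
      starts <- c(starts, cur_start); ends <- c(ends, cur_end)
      cur_start <- cur_end <- r
    }
  }
  data.frame(start = c(starts, cur_start), end = c(ends, cur_end))
}

# Ideal alpha-helix Calpha-only chain as a structure3d (1.5 A rise,
# 100 degrees per residue).
ca_only_helix <- function(n, chain = "A") {
  j <- seq_len(n) - 1
  structure3d(data.frame(
    chain = chain, resno = seq_len(n), resid = "ALA", elety = "CA",
    element = "C",
    x = 2.3 * cos(j * 100 * pi / 180),
    y = 2.3 * sin(j * 100 * pi / 180),
    z = 1.5 * j))
}

# Fully extended Calpha-only chain.
ca_only_extended <- function(n, chain = "A") {
  structure3d(data.frame(
    chain = chain, resno = seq_len(n), resid = "ALA", elety = "CA",
    element = "C", x = 3.8 * seq_len(n), y = 0, z = 0))
}

# Default docked fixture shared by docking/PRE tests (built once per run).
fixture_docked_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sol <- make_solenoid(solenoid_spec(seed = 42))
      units <- decompose_overlapping_ubas(assign_helices(sol$structure))
      tmpl <- make_template_complex(seed = 44)
      cache <<- list(sol = sol, units = units, template = tmpl,
                     model = dock_ubiquitins(sol$structure, units, tmpl))
    }
    cache
  }
})

# Minimal hand-built two-copy model for linkage geometry tests: copy U1
# with Lys NZ at the origin and Gly76 C far away, copy U2 with Gly76 C at
# distance `d` from U1's NZ and its own NZ far away.
fake_linkage_pair <- function(d, lys = 48L) {
  atoms <- data.frame(
    chain = c("U1", "U1", "U2", "U2"),
    resno = c(lys, 76L, lys, 76L),
    resid = c("LYS", "GLY", "LYS", "GLY"),
    elety = c("NZ", "C", "NZ", "C"),
    element = c("N", "C", "N", "C"),
    x = c(0, 500, 900, d), y = 0, z = 0)
  structure(list(structure = structure3d(atoms),
                 receptor_chains = character(0),
                 placements = data.frame(unit = 1:2,
                                         chain = c("U1", "U2"),
                                         rmsd = 0),
                 transforms = list(), footprints = list()),
            class = "docked_model")
}
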