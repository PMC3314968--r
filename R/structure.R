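#' Coordinate model
#'
#' A `structure3d` is a light container for a single-model set of atomic
#' coordinates: one data frame with columns `chain`, `resno`, `resid`
#' (three-letter residue name), `elety` (atom name), `element`, `x`, `y`,
#' `z` (Angstrom), `o` (occupancy) and `b` (B-factor). Residue numbers are
#' 1-based and must be non-decreasing within a chain; coordinates must be
#' finite.
#'
#' @param atoms data frame with the columns listed above.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms) {
  required <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty model: no atoms")
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  atoms$resno <- as.integer(atoms$resno)
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    if (any(diff(rn) < 0))
      stop("residue numbers decrease within chain ", ch)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  nres <- sum(!duplicated(a[, c("chain", "resno")]))
  cat(sprintf("structure3d: %d atoms, %d residues, chains: %s\n",
              nrow(a), nres, paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records of a single-model PDB file (via bio3d) into a
#' [structure3d]. Duplicate atom serial numbers are accepted with a warning.
#'
#' @param path path to a PDB file.
#' @return A [structure3d].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty model in ", path)
  if (anyDuplicated(at$eleno))
    warning("duplicate atom serial numbers in ", path)
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  element <- at$elesy
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  bad <- is.na(element) | trimws(element) == ""
  element[bad] <- guess[bad]
  structure3d(data.frame(
    chain = chain, resno = at$resno, resid = at$resid,
    elety = at$elety, element = trimws(element),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE))
}

#' Write a PDB file
#'
#' Writes a [structure3d] as ATOM records (coordinates to 3 decimals, the PDB
#' fixed-column convention). The B-factor column can first be loaded with
#' per-residue quantities (e.g. CSPs) for visualisation.
#'
#' @param s a [structure3d].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   o = a$o, b = a$b)
  invisible(path)
}

#' One-letter sequence of a chain
#'
#' @param s a [structure3d].
#' @param chain chain identifier (default: first chain).
#' @return Single string of one-letter residue codes (`X` for non-standard).
#' @export
chain_sequence <- function(s, chain = NULL) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no such chain: ", chain)
  res <- a[!duplicated(a$resno), , drop = FALSE]
  paste(bio3d::aa321(res$resid), collapse = "")
}

## internal: n x 3 coordinate matrix for selected atoms
atom_coords <- function(s, chain = NULL, elety = NULL, resno = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  out <- as.matrix(a[keep, c("x", "y", "z"), drop = FALSE])
  rownames(out) <- NULL
  out
}

## internal: xyz of a single named atom; error mentions what is missing
atom_xyz <- function(s, chain, resno, elety, what = NULL) {
  a <- s$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)
  if (length(i) == 0)
    stop("missing atom ", elety, " in residue ", resno, " of chain ", chain,
         if (!is.null(what)) paste0(" (", what, ")"), call. = FALSE)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Rigid-body transformation
#'
#' A proper rotation (3x3, det = +1) plus a translation (Angstrom), applied
#' to row-vector coordinates as `x %*% t(R) + t`.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation length-3 numeric translation vector.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation determinant is not +1 (improper rotation)")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transformation
#'
#' @param x a [structure3d] or an n x 3 coordinate matrix.
#' @param tf a [rigid_transform].
#' @return Object of the same type as `x`, with transformed coordinates.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "structure3d")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    new <- xyz %*% t(tf$R) + matrix(tf$t, nrow(xyz), 3, byrow = TRUE)
    x$atoms$x <- new[, 1]; x$atoms$y <- new[, 2]; x$atoms$z <- new[, 3]
    return(x)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinate matrix must have 3 columns")
  x %*% t(tf$R) + matrix(tf$t, nrow(x), 3, byrow = TRUE)
}

#' Invert a rigid transformation
#'
#' @param tf a [rigid_transform].
#' @return The inverse [rigid_transform].
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t))
}

#' Compose two rigid transformations
#'
#' Returns the transform equivalent to applying `first` then `second`.
#'
#' @param first,second [rigid_transform] objects.
#' @return A [rigid_transform].
#' @export
compose_transform <- function(second, first) {
  rigid_transform(second$R %*% first$R,
                  as.numeric(second$R %*% first$t) + second$t)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinates, by SVD of the covariance matrix with a sign flip of
#' the smallest singular direction when the optimum would be a reflection.
#'
#' @param mobile n x 3 matrix of coordinates to move (n >= 3).
#' @param reference n x 3 matrix of paired target coordinates.
#' @return List with `transform` (a [rigid_transform] mapping `mobile` onto
#'   `reference`) and `rmsd` (Angstrom, after superposition).
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  if (ncol(P) != 3 || ncol(Q) != 3) stop("coordinates must be n x 3")
  if (nrow(P) != nrow(Q)) stop("point counts differ")
  if (nrow(P) < 3) stop("need at least 3 paired points")
  pm <- colMeans(P); qm <- colMeans(Q)
  Pc <- sweep(P, 2, pm); Qc <- sweep(Q, 2, qm)
  scale <- max(1, max(abs(Pc)), max(abs(Qc)))
  if (svd(Pc)$d[2] < 1e-8 * scale || svd(Qc)$d[2] < 1e-8 * scale)
    stop("degenerate geometry: points are collinear")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- qm - as.numeric(R %*% pm)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(transform = rigid_transform(R, tr), rmsd = rmsd)
}

#' Assign alpha-helices from Calpha geometry
#'
#' A residue window is helical when the Calpha(i)-Calpha(i+3) distance lies
#' in \[4.5, 5.6\] A and the Calpha(i)-Calpha(i+4) distance in \[5.8, 6.8\] A.
#' Maximal runs of helical windows over consecutively numbered residues are
#' reported as segments spanning the full window extent; segments shorter
#' than `min_length` residues are dropped and overlaps are resolved in
#' favour of the N-terminal segment.
#'
#' @param s a [structure3d].
#' @param chain chains to scan (default: all).
#' @param min_length minimum helix length in residues (default 6).
#' @return Data frame with columns `chain`, `start`, `end`, `length`, and an
#'   `axes` attribute (one N-to-C unit axis vector per segment, by row).
#' @export
assign_helices <- function(s, chain = NULL, min_length = 6) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  chains <- if (is.null(chain)) unique(a$chain) else chain
  segs <- list(); axes <- list()
  for (ch in chains) {
    sub <- a[a$chain == ch, , drop = FALSE]
    res <- unique(sub$resno)
    ca <- sub[sub$elety == "CA", , drop = FALSE]
    no_ca <- setdiff(res, ca$resno)
    if (length(no_ca) > 0)
      stop("missing Calpha atoms in chain ", ch, " for residues: ",
           paste(no_ca, collapse = ", "))
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
    n <- nrow(ca)
    if (n < min_length) next
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    dist_k <- function(k) {
      i <- seq_len(n - k)
      sqrt(rowSums((xyz[i + k, , drop = FALSE] - xyz[i, , drop = FALSE])^2))
    }
    d3 <- dist_k(3); d4 <- dist_k(4)
    consec <- function(k) ca$resno[seq_len(n - k) + k] - ca$resno[seq_len(n - k)] == k
    ok <- d3[seq_len(n - 4)] >= 4.5 & d3[seq_len(n - 4)] <= 5.6 &
      d4 >= 5.8 & d4 <= 6.8 & consec(4)[seq_len(n - 4)]
    if (!any(ok)) next
    r <- rle(ok)
    pos_end <- cumsum(r$lengths)
    pos_start <- pos_end - r$lengths + 1
    prev_end <- -Inf
    for (j in which(r$values)) {
      i0 <- pos_start[j]; i1 <- pos_end[j] + 4L
      start <- ca$resno[i0]; end <- ca$resno[i1]
      if (start <= prev_end) start <- prev_end + 1L  # yield to N-terminal segment
      if (end - start + 1 < min_length) next
      i0 <- match(start, ca$resno)
      axis <- helix_axis(xyz[i0:i1, , drop = FALSE])
      segs[[length(segs) + 1L]] <- data.frame(
        chain = ch, start = start, end = end, length = end - start + 1L,
        stringsAsFactors = FALSE)
      axes[[length(axes) + 1L]] <- axis
      prev_end <- end
    }
  }
  out <- if (length(segs) == 0) {
    data.frame(chain = character(), start = integer(), end = integer(),
               length = integer(), stringsAsFactors = FALSE)
  } else do.call(rbind, segs)
  rownames(out) <- NULL
  attr(out, "axes") <- if (length(axes)) do.call(rbind, axes) else
    matrix(numeric(), 0, 3)
  class(out) <- c("helix_segments", "data.frame")
  out
}

## internal: principal-axis unit vector of Calpha coordinates, oriented N->C
helix_axis <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(c0)$v[, 1]
  if (sum(v * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Decompose a helix list into overlapping UBA units
#'
#' A solenoid of n helices (n odd, >= 3) contains (n-1)/2 three-helix UBA
#' units in which the third helix of unit i is the first helix of unit i+1.
#'
#' @param helices output of [assign_helices] (must all be one chain and
#'   ordered by sequence).
#' @return Data frame with columns `unit`, `h1`, `h2`, `h3` (helix indices),
#'   `start`, `end` (residue span); the helix table is kept in attribute
#'   `helices` for downstream docking.
#' @export
decompose_overlapping_ubas <- function(helices) {
  n <- nrow(helices)
  if (n < 3 || n %% 2 == 0)
    stop("an overlapping-UBA solenoid requires an odd helix count >= 3, got ", n)
  k <- (n - 1L) / 2L
  units <- data.frame(
    unit = seq_len(k),
    h1 = 2L * seq_len(k) - 1L, h2 = 2L * seq_len(k), h3 = 2L * seq_len(k) + 1L)
  units$start <- helices$start[units$h1]
  units$end <- helices$end[units$h3]
  attr(units, "helices") <- helices
  class(units) <- c("uba_units", "data.frame")
  units
}

#' Scan a sequence for UBA signature motifs
#'
#' Finds non-overlapping, left-to-right matches of the UBA signature
#' (M/L)-G-(Y/F), including the K-G-F variant found in degenerate second
#' units, i.e. the pattern `[MLK]G[FY]`.
#'
#' @param sequence one-letter amino-acid string (standard 20-letter alphabet).
#' @return Data frame with columns `position` (1-based start) and `motif`.
#' @export
scan_signature_motifs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq <- toupper(sequence)
  ok <- strsplit(seq, "")[[1]] %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(ok))
    stop("illegal amino-acid character at position ", which(!ok)[1])
  m <- gregexpr("[MLK]G[FY]", seq)[[1]]
  if (m[1] == -1)
    return(data.frame(position = integer(), motif = character()))
  data.frame(position = as.integer(m),
             motif = substring(seq, m, m + 2L),
             stringsAsFactors = FALSE)
}

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences (gaps removed).
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aln <- bio3d::read.fasta(path)
  out <- apply(aln$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  names(out) <- aln$id
  toupper(out)
}
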