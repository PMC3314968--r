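#' Template UBA:ubiquitin complex
#'
#' A two-chain structure holding a three-helix UBA domain in complex with
#' ubiquitin, used as the superposition template for docking. The contact
#' footprint (UBA residues with a heavy atom within `contact_cutoff` of the
#' ubiquitin chain) is recorded so that docked copies can have their modelled
#' interface excluded from clash reports.
#'
#' @param s a [structure3d] containing both chains.
#' @param uba_chain,ub_chain chain identifiers of the UBA and ubiquitin.
#' @param helices helix segments of the UBA chain (exactly 3), as returned
#'   by [assign_helices].
#' @param contact_cutoff heavy-atom distance defining the footprint, A.
#' @return Object of class `template_complex`.
#' @export
template_complex <- function(s, uba_chain, ub_chain, helices,
                             contact_cutoff = 5.0) {
  stopifnot(inherits(s, "structure3d"))
  if (!all(c(uba_chain, ub_chain) %in% s$atoms$chain))
    stop("template must contain both the UBA and the ubiquitin chain")
  if (nrow(helices) != 3)
    stop("template UBA must have exactly 3 helices, got ", nrow(helices))
  a <- heavy_atoms(s$atoms)
  ua <- a[a$chain == uba_chain, , drop = FALSE]
  ub <- a[a$chain == ub_chain, , drop = FALSE]
  d <- cross_dist(as.matrix(ua[, c("x", "y", "z")]),
                  as.matrix(ub[, c("x", "y", "z")]))
  contact <- apply(d, 1, min) <= contact_cutoff
  structure(list(structure = s, uba_chain = uba_chain, ub_chain = ub_chain,
                 helices = helices,
                 footprint = sort(unique(ua$resno[contact]))),
            class = "template_complex")
}

## internal helpers
heavy_atoms <- function(atoms) atoms[toupper(atoms$element) != "H", , drop = FALSE]

cross_dist <- function(A, B) {
  # pairwise Euclidean distances, nrow(A) x nrow(B)
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

## internal: centred pairing of two helices, trimmed to the shorter one.
## Returns a data frame (t_res, r_res) of paired residue numbers.
pair_helix_residues <- function(t_start, t_end, r_start, r_end) {
  tr <- t_start:t_end; rr <- r_start:r_end
  m <- min(length(tr), length(rr))
  toff <- (length(tr) - m) %/% 2
  roff <- (length(rr) - m) %/% 2
  data.frame(t_res = tr[toff + seq_len(m)], r_res = rr[roff + seq_len(m)])
}

#' Dock monoubiquitins onto a solenoid by per-UBA template superposition
#'
#' For each overlapping-UBA unit of the receptor, the template UBA is
#' superposed onto the unit (helix k of the template paired with helix k of
#' the unit, Calpha pairs taken from helix midpoints outward, trimmed to
#' the shorter helix) and the resulting rigid transform is applied to the
#' template's ubiquitin, which is added to the model as a new chain `U<i>`.
#'
#' @param receptor a [structure3d] carrying the solenoid.
#' @param units UBA units from [decompose_overlapping_ubas] (the receptor
#'   helix table rides along as an attribute).
#' @param template a [template_complex].
#' @return Object of class `docked_model`: `structure` (receptor plus
#'   placed copies), `receptor_chains`, `placements` (unit, chain, rmsd),
#'   `transforms` and per-copy `footprints` (receptor chain/residue pairs
#'   corresponding to the template contact footprint).
#' @export
dock_ubiquitins <- function(receptor, units, template) {
  stopifnot(inherits(receptor, "structure3d"),
            inherits(template, "template_complex"))
  helices <- attr(units, "helices")
  if (is.null(helices)) stop("units carry no helix table")
  ts <- template$structure
  ub_atoms <- ts$atoms[ts$atoms$chain == template$ub_chain, , drop = FALSE]
  receptor_chains <- unique(receptor$atoms$chain)
  combined <- receptor$atoms
  placements <- list(); transforms <- list(); footprints <- list()
  for (i in seq_len(nrow(units))) {
    h_idx <- c(units$h1[i], units$h2[i], units$h3[i])
    pairs <- list()
    for (k in 1:3) {
      th <- template$helices[k, ]
      rh <- helices[h_idx[k], ]
      p <- pair_helix_residues(th$start, th$end, rh$start, rh$end)
      if (nrow(p) < 3)
        stop("unit ", units$unit[i], ": helix ", k,
             " has fewer than 3 pairable residues")
      p$chain <- rh$chain
      pairs[[k]] <- p
    }
    pairs <- do.call(rbind, pairs)
    mob <- t(vapply(seq_len(nrow(pairs)), function(j)
      atom_xyz(ts, template$uba_chain, pairs$t_res[j], "CA",
               "template helix"), numeric(3)))
    ref <- t(vapply(seq_len(nrow(pairs)), function(j)
      atom_xyz(receptor, pairs$chain[j], pairs$r_res[j], "CA",
               paste("unit", units$unit[i])), numeric(3)))
    sup <- kabsch_superpose(mob, ref)
    placed <- ub_atoms
    new_xyz <- apply_transform(as.matrix(placed[, c("x", "y", "z")]),
                               sup$transform)
    placed$x <- new_xyz[, 1]; placed$y <- new_xyz[, 2]; placed$z <- new_xyz[, 3]
    chain_id <- paste0("U", units$unit[i])
    placed$chain <- chain_id
    combined <- rbind(combined, placed)
    placements[[i]] <- data.frame(unit = units$unit[i], chain = chain_id,
                                  rmsd = sup$rmsd, stringsAsFactors = FALSE)
    transforms[[chain_id]] <- sup$transform
    in_fp <- pairs$t_res %in% template$footprint
    footprints[[chain_id]] <- data.frame(chain = pairs$chain[in_fp],
                                         resno = pairs$r_res[in_fp],
                                         stringsAsFactors = FALSE)
  }
  structure(list(structure = structure3d(combined),
                 receptor_chains = receptor_chains,
                 placements = do.call(rbind, placements),
                 transforms = transforms, footprints = footprints),
            class = "docked_model")
}

#' @export
print.docked_model <- function(x, ...) {
  cat(sprintf("docked_model: %d placed ubiquitin cop%s on receptor chain(s) %s\n",
              nrow(x$placements), if (nrow(x$placements) == 1) "y" else "ies",
              paste(x$receptor_chains, collapse = " ")))
  print(x$placements)
  invisible(x)
}

#' Detect inter-chain steric clashes
#'
#' Reports all heavy-atom pairs from different chains closer than `cutoff`.
#' For a [docked_model] with `exclude_footprint = TRUE`, contacts between a
#' placed ubiquitin and the receptor residues of its own template-defined
#' interface footprint are not counted: that contact is the modelled
#' interface, not a clash.
#'
#' @param x a `docked_model` or a plain [structure3d].
#' @param cutoff clash distance, A (default 2.4).
#' @param exclude_footprint exclude each copy's own interface footprint
#'   (default TRUE; ignored for plain structures).
#' @return Object of class `clash_report`: `contacts` (chain1, resno1,
#'   elety1, chain2, resno2, elety2, distance) and `counts` per chain pair.
#' @export
detect_clashes <- function(x, cutoff = 2.4, exclude_footprint = TRUE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (inherits(x, "docked_model")) {
    s <- x$structure
    footprints <- if (exclude_footprint) x$footprints else list()
  } else if (inherits(x, "structure3d")) {
    s <- x
    footprints <- list()
  } else stop("x must be a docked_model or structure3d")
  a <- heavy_atoms(s$atoms)
  chains <- sort(unique(a$chain))
  contacts <- list()
  counts <- list()
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (j <= i) next
    c1 <- chains[i]; c2 <- chains[j]
    a1 <- a[a$chain == c1, , drop = FALSE]
    a2 <- a[a$chain == c2, , drop = FALSE]
    d <- cross_dist(as.matrix(a1[, c("x", "y", "z")]),
                    as.matrix(a2[, c("x", "y", "z")]))
    hit <- which(d < cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      df <- data.frame(chain1 = c1, resno1 = a1$resno[hit[, 1]],
                       elety1 = a1$elety[hit[, 1]],
                       chain2 = c2, resno2 = a2$resno[hit[, 2]],
                       elety2 = a2$elety[hit[, 2]],
                       distance = d[hit], stringsAsFactors = FALSE)
      for (copy in names(footprints)) {
        fp <- footprints[[copy]]
        if (nrow(fp) == 0) next
        key <- paste(fp$chain, fp$resno)
        drop1 <- df$chain2 == copy & paste(df$chain1, df$resno1) %in% key
        drop2 <- df$chain1 == copy & paste(df$chain2, df$resno2) %in% key
        df <- df[!(drop1 | drop2), , drop = FALSE]
      }
    } else {
      df <- data.frame(chain1 = character(), resno1 = integer(),
                       elety1 = character(), chain2 = character(),
                       resno2 = integer(), elety2 = character(),
                       distance = numeric(), stringsAsFactors = FALSE)
    }
    contacts[[paste(c1, c2)]] <- df
    counts[[paste(c1, c2)]] <- data.frame(chain1 = c1, chain2 = c2,
                                          n_clashes = nrow(df),
                                          stringsAsFactors = FALSE)
  }
  contacts <- do.call(rbind, c(contacts, list(make.row.names = FALSE)))
  counts <- do.call(rbind, c(counts, list(make.row.names = FALSE)))
  if (is.null(contacts))
    contacts <- data.frame(chain1 = character(), resno1 = integer(),
                           elety1 = character(), chain2 = character(),
                           resno2 = integer(), elety2 = character(),
                           distance = numeric())
  structure(list(contacts = contacts, counts = counts, cutoff = cutoff),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("clash_report: %d heavy-atom pair(s) below %.2f A\n",
              nrow(x$contacts), x$cutoff))
  if (!is.null(x$counts) && nrow(x$counts) > 0)
    print(x$counts[x$counts$n_clashes > 0, , drop = FALSE])
  invisible(x)
}

#' Assess K48/K63 isopeptide-linkage feasibility between adjacent copies
#'
#' For each pair of ubiquitins docked on consecutive UBA units, measures the
#' distance between the Lys48 (or Lys63) side-chain NZ of one copy and the
#' Gly76 carbonyl C of the other, in both directions, and reports the
#' minimum. A pair is feasible when that distance is at or below
#' `threshold` (default 9 A: an isopeptide bond of ~1.3 A plus the reach of
#' the flexible C-terminal tail, residues 72-76).
#'
#' @param model a `docked_model` with at least 2 placed copies.
#' @param linkage `"K48"` or `"K63"`.
#' @param threshold feasibility distance, A.
#' @return Data frame with columns `chain_a`, `chain_b`, `linkage`,
#'   `distance` and `feasible`.
#' @export
assess_linkage <- function(model, linkage = c("K48", "K63"), threshold = 9.0) {
  stopifnot(inherits(model, "docked_model"))
  linkage <- match.arg(linkage)
  if (nrow(model$placements) < 2)
    stop("need at least 2 placed ubiquitins")
  lys <- if (linkage == "K48") 48L else 63L
  pl <- model$placements[order(model$placements$unit), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(pl) - 1)) {
    ca <- pl$chain[i]; cb <- pl$chain[i + 1]
    d_ab <- sqrt(sum((atom_xyz(model$structure, ca, lys, "NZ",
                               paste("copy", ca)) -
                      atom_xyz(model$structure, cb, 76L, "C",
                               paste("copy", cb)))^2))
    d_ba <- sqrt(sum((atom_xyz(model$structure, cb, lys, "NZ",
                               paste("copy", cb)) -
                      atom_xyz(model$structure, ca, 76L, "C",
                               paste("copy", ca)))^2))
    d <- min(d_ab, d_ba)
    out[[i]] <- data.frame(chain_a = ca, chain_b = cb, linkage = linkage,
                           distance = d, feasible = d <= threshold,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
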