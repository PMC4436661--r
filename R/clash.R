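# Steric clash detection and the clashes-per-1000-atoms score.
#
# The score counts non-bonded atom pairs whose van der Waals spheres overlap
# by at least `threshold` (default 0.4 A).  It follows the familiar
# clashes/1000-atoms convention of model-quality control; agreement with
# dot-probe implementations that add hydrogens first is approximate when
# models carry no hydrogens.

#' Find steric clashes
#'
#' Reports all atom pairs with `(r_a + r_b) - d >= threshold`, where r are
#' van der Waals radii (C 1.70, N 1.55, O 1.52, P 1.80, H 1.20 A), except:
#' pairs separated by at most 3 covalent bonds (within a residue or across
#' the O3'-P backbone linkage), and N/O-N/O pairs at d >= 2.6 A, which are
#' treated as hydrogen bonds rather than clashes (disable with
#' `hbond_exempt = FALSE`).  Candidate pairs come from a spatial grid; the
#' result is independent of the grid cell size.
#'
#' @param model An `rna_structure`.
#' @param threshold Minimum overlap in Angstrom to call a clash.
#' @param hbond_exempt Exempt long N/O-N/O contacts as hydrogen bonds.
#' @param cell Grid cell size in Angstrom (default: maximum contact
#'   distance); the output never depends on it.
#' @return Tibble of clashes: `atom_a`, `atom_b` (key + atom name),
#'   `distance`, `overlap`, ordered deterministically.
#' @export
find_clashes <- function(model, threshold = 0.4, hbond_exempt = TRUE,
                         cell = NULL) {
  stopifnot(inherits(model, "rna_structure"))
  atoms <- model$atoms
  empty <- tibble(atom_a = character(0), atom_b = character(0),
                  distance = numeric(0), overlap = numeric(0))
  if (nrow(atoms) < 2) return(empty)
  radii <- unname(.vdw_radii[atoms$elem])
  radii[is.na(radii)] <- 1.70
  max_contact <- 2 * max(radii) - threshold
  if (is.null(cell)) cell <- max_contact
  xyz <- coord_matrix(atoms)

  cand <- grid_candidate_pairs(xyz, cell, max_contact)
  if (nrow(cand) == 0) return(empty)
  d <- sqrt(rowSums((xyz[cand[, 1], , drop = FALSE] -
                       xyz[cand[, 2], , drop = FALSE])^2))
  overlap <- radii[cand[, 1]] + radii[cand[, 2]] - d
  keep <- overlap >= threshold - 1e-9   # boundary overlaps count as clashes
  cand <- cand[keep, , drop = FALSE]
  d <- d[keep]; overlap <- overlap[keep]
  if (nrow(cand) == 0) return(empty)

  # bonded exclusions: graph distance <= 3
  near <- bonded_within3(model)
  excl <- paste(cand[, 1], cand[, 2]) %in% near
  # hydrogen-bond exemption
  if (hbond_exempt) {
    no <- atoms$elem[cand[, 1]] %in% c("N", "O") &
      atoms$elem[cand[, 2]] %in% c("N", "O")
    excl <- excl | (no & d >= 2.6)
  }
  cand <- cand[!excl, , drop = FALSE]
  d <- d[!excl]; overlap <- overlap[!excl]
  if (nrow(cand) == 0) return(empty)

  lab <- paste0(atoms$key, "/", atoms$atom)
  out <- tibble(atom_a = lab[cand[, 1]], atom_b = lab[cand[, 2]],
                distance = d, overlap = overlap)
  out[order(cand[, 1], cand[, 2]), ]
}

# candidate index pairs (i < j) within max_contact, via spatial binning
grid_candidate_pairs <- function(xyz, cell, max_contact) {
  reach <- ceiling(max_contact / cell)
  g <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  keymul <- c(1, max(g[, 1]) + 2 * reach + 2, 0)
  keymul[3] <- keymul[2] * (max(g[, 2]) + 2 * reach + 2)
  cellkey <- function(gx, gy, gz) gx + keymul[2] * gy + keymul[3] * gz
  key <- cellkey(g[, 1], g[, 2], g[, 3])
  by_cell <- split(seq_len(nrow(xyz)), key)
  offsets <- expand.grid(dx = -reach:reach, dy = -reach:reach, dz = 0:reach)
  # half-space of offsets to visit each cell pair once
  offsets <- offsets[offsets$dz > 0 |
                       (offsets$dz == 0 & (offsets$dy > 0 |
                                             (offsets$dy == 0 & offsets$dx >= 0))), ]
  out <- vector("list", nrow(offsets))
  for (r in seq_len(nrow(offsets))) {
    nk <- cellkey(g[, 1] + offsets$dx[r], g[, 2] + offsets$dy[r],
                  g[, 3] + offsets$dz[r])
    tgt <- by_cell[as.character(nk)]
    ns <- lengths(tgt)
    has <- ns > 0
    if (!any(has)) next
    i <- rep(seq_len(nrow(xyz))[has], ns[has])
    j <- unlist(tgt[has], use.names = FALSE)
    if (offsets$dx[r] == 0 && offsets$dy[r] == 0 && offsets$dz[r] == 0) {
      keep <- i < j
    } else {
      keep <- rep(TRUE, length(i))
    }
    pair <- cbind(pmin(i[keep], j[keep]), pmax(i[keep], j[keep]))
    out[[r]] <- pair
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs) || nrow(pairs) == 0) return(matrix(integer(0), 0, 2))
  unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
}

# "i j" labels of atom pairs within 3 covalent bonds (intra-residue bonds,
# plus the O3'(i)-P(i+1) bridge when the two residues are consecutive in a
# chain and the linkage distance is plausible)
bonded_within3 <- function(model) {
  atoms <- model$atoms
  n <- nrow(atoms)
  aid <- paste(atoms$key, atoms$atom)
  idx <- setNames(seq_len(n), aid)

  edges <- list()
  res <- residues(model)
  for (k in seq_len(nrow(res))) {
    b <- residue_bonds(res$base[k])
    i1 <- idx[paste(res$key[k], b[, 1])]
    i2 <- idx[paste(res$key[k], b[, 2])]
    ok <- !is.na(i1) & !is.na(i2)
    edges[[length(edges) + 1]] <- cbind(i1[ok], i2[ok])
  }
  # hydrogens: attach to their parent heavy atom by name
  hyd <- which(atoms$elem == "H")
  if (length(hyd) > 0) {
    hi <- vapply(hyd, function(i) {
      for (p in hydrogen_parent_candidates(atoms$atom[i])) {
        j <- idx[paste(atoms$key[i], p)]
        if (!is.na(j)) return(j)
      }
      NA_integer_
    }, integer(1))
    ok <- !is.na(hi)
    edges[[length(edges) + 1]] <- cbind(hyd[ok], hi[ok])
  }
  # backbone bridges
  for (k in seq_len(nrow(res) - 1)) {
    if (res$chain[k] != res$chain[k + 1]) next
    o3 <- idx[paste(res$key[k], "O3'")]
    p <- idx[paste(res$key[k + 1], "P")]
    if (is.na(o3) || is.na(p)) next
    dd <- sqrt(sum((coord_matrix(atoms[o3, ]) - coord_matrix(atoms[p, ]))^2))
    if (dd <= 2.5) edges[[length(edges) + 1]] <- cbind(o3, p)
  }
  em <- do.call(rbind, edges)
  adj <- vector("list", n)
  if (!is.null(em) && nrow(em) > 0) {
    for (r in seq_len(nrow(em))) {
      adj[[em[r, 1]]] <- c(adj[[em[r, 1]]], em[r, 2])
      adj[[em[r, 2]]] <- c(adj[[em[r, 2]]], em[r, 1])
    }
  }
  # breadth-first to depth 3
  out <- character(0)
  for (i in seq_len(n)) {
    d1 <- adj[[i]]
    d2 <- unique(unlist(adj[d1], use.names = FALSE))
    d3 <- unique(unlist(adj[d2], use.names = FALSE))
    nb <- setdiff(unique(c(d1, d2, d3)), i)
    nb <- nb[nb > i]
    if (length(nb) > 0) out <- c(out, paste(i, nb))
  }
  out
}

# candidate heavy-atom names a hydrogen may be bonded to, best first
# (H5' -> C5'; H2' -> C2'; HO2' -> O2'; H61/H62 -> N6; H8 -> C8; ...)
hydrogen_parent_candidates <- function(h) {
  if (startsWith(h, "HO")) return(paste0("O", substring(h, 3)))
  core <- sub("''$", "'", substring(h, 2))
  trimmed <- sub("[0-9]$", "", core)
  unique(c(paste0(c("C", "N", "O"), core),
           paste0(c("C", "N", "O"), trimmed)))
}

#' Export a clash list as CSV
#'
#' @param x Output of [find_clashes()].
#' @param path Output CSV path.
#' @return Invisibly, the exported tibble (distances/overlaps at 4
#'   decimals).
#' @export
write_clashes <- function(x, path) {
  out <- x
  out$distance <- round(out$distance, 4)
  out$overlap <- round(out$overlap, 4)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(out)
}

#' Clash Score
#'
#' Number of steric clashes per 1000 atoms, over all retained atoms.  Low
#' values indicate physically plausible geometry; the score is used as a
#' control alongside accuracy metrics because a model can match a reference
#' globally while being sterically impossible locally.
#'
#' @inheritParams find_clashes
#' @return Single number: `1000 * n_clashes / atom_count`, with attributes
#'   `n_clashes`, `n_atoms` and `has_hydrogens` (the score is sensitive to
#'   whether hydrogens are present).
#' @export
clash_score <- function(model, threshold = 0.4, hbond_exempt = TRUE) {
  stopifnot(inherits(model, "rna_structure"))
  if (atom_count(model) == 0) abort("empty model")
  cl <- find_clashes(model, threshold = threshold, hbond_exempt = hbond_exempt)
  score <- 1000 * nrow(cl) / atom_count(model)
  structure(score, n_clashes = nrow(cl), n_atoms = atom_count(model),
            has_hydrogens = has_hydrogens(model))
}
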