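# Shared fixtures and independent oracles for the test suite.

# small duplex used across tests (built once)
fixture_duplex <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_helix("GGCGCAAUCC")
    cache
  }
})

# ~2200-atom duplex for sampling-based checks
fixture_big_duplex <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_helix(paste(rep("GCAU", 13), collapse = ""))
    }
    cache
  }
})

identity_correspondence <- function(model) {
  build_correspondence(model, model, mode = "by-index")
}

# combine two structures into one (relabelling the second's chains)
combine_structures <- function(a, b, chain_offset = c(A = "C", B = "D"),
                               label = "combined") {
  bb <- b$atoms
  bb$chain <- unname(chain_offset[bb$chain])
  bb$serial <- bb$serial + max(a$atoms$serial)
  new_rna_structure(dplyr::bind_rows(a$atoms, bb), label = label)
}

random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    if (sqrt(sum(q^2)) > 1e-3) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# --- independent oracles ------------------------------------------------

# quaternion characteristic-polynomial superposition oracle (Horn): minimal
# RMSD from the largest eigenvalue of the 4x4 key matrix, no rotation matrix
# construction shared with the implementation under test
quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- t(Qc) %*% Pc
  tr <- function(i, j) S[i, j]
  K <- matrix(c(
    tr(1,1)+tr(2,2)+tr(3,3), tr(2,3)-tr(3,2), tr(3,1)-tr(1,3), tr(1,2)-tr(2,1),
    tr(2,3)-tr(3,2), tr(1,1)-tr(2,2)-tr(3,3), tr(1,2)+tr(2,1), tr(3,1)+tr(1,3),
    tr(3,1)-tr(1,3), tr(1,2)+tr(2,1), -tr(1,1)+tr(2,2)-tr(3,3), tr(2,3)+tr(3,2),
    tr(1,2)-tr(2,1), tr(3,1)+tr(1,3), tr(2,3)+tr(3,2), -tr(1,1)-tr(2,2)+tr(3,3)
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ssd <- sum(Pc^2) + sum(Qc^2) - 2 * lambda
  sqrt(max(0, ssd) / nrow(P))
}

# brute-force O(n^2) clash oracle; own radii and hydrogen-bond rule, bonded
# exclusions delegated to the package's bond graph (the graph itself is
# exercised by the trivial-exclusion tests)
allpairs_clashes <- function(model, threshold = 0.4, hbond_exempt = TRUE) {
  atoms <- model$atoms
  radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, H = 1.20)[atoms$elem]
  radii[is.na(radii)] <- 1.70
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  d <- as.matrix(stats::dist(xyz))
  ov <- outer(radii, radii, "+") - d
  hits <- which(upper.tri(ov) & ov >= threshold, arr.ind = TRUE)
  if (nrow(hits) == 0) return(hits)
  excl <- rnassess:::bonded_within3(model)
  keep <- !(paste(hits[, 1], hits[, 2]) %in% excl)
  if (hbond_exempt) {
    no <- atoms$elem[hits[, 1]] %in% c("N", "O") &
      atoms$elem[hits[, 2]] %in% c("N", "O")
    dd <- d[hits]
    keep <- keep & !(no & dd >= 2.6)
  }
  hits[keep, , drop = FALSE]
}

# format one properly aligned PDB ATOM record
pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, b = 0, elem = substr(name, 1, 1), alt = " ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resid, chain, resno, x, y, z, occ, b, elem)
}

# hand-written single-nucleotide PDB text (guanosine, 23 heavy atoms)
one_nt_pdb_lines <- function() {
  tpl <- build_helix("G", single_strand = TRUE)
  write_pdb(tpl)
}

# face-to-face pair of two template nucleotides in WC-like geometry
# (second base flipped about the pair-frame dyad), e.g. a GU wobble
make_face_pair <- function(b1, b2) {
  tpl <- rnassess:::aform_templates()
  place <- function(base, flip, chain) {
    t0 <- tpl[[base]]
    xyz <- rnassess:::helix_place(cbind(t0$x, t0$y, t0$z), 0, flip)
    tibble::tibble(chain = chain, resno = 1L, icode = "", resid = base,
                   base = base, atom = t0$atom, elem = t0$elem,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occ = 1, b = 0, serial = 0L)
  }
  atoms <- dplyr::bind_rows(place(b1, FALSE, "A"), place(b2, TRUE, "B"))
  atoms$serial <- seq_len(nrow(atoms))
  new_rna_structure(atoms, label = paste0("pair-", b1, b2))
}
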