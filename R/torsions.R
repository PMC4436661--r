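#' Signed dihedral angle
#'
#' Torsion angle of four points via the atan2 formulation, in degrees in
#' (-180, 180].  Inputs may be single points (length-3 vectors) or n x 3
#' matrices (vectorised over rows).  Degenerate geometry (coincident points
#' or a collinear triple) yields `NA`.
#'
#' @param p1,p2,p3,p4 Points or coordinate matrices.
#' @return Numeric vector of angles in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross_rows <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  m1 <- cross_rows(n1, b2 / b2n)
  # IUPAC sign convention: clockwise rotation of the far bond, viewed along
  # the central bond, is positive
  ang <- -atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  bad <- rowSums(n1^2) < 1e-12 | rowSums(n2^2) < 1e-12 | b2n < 1e-9
  ang[bad] <- NA_real_
  # convention: report 180, not -180
  ang[!is.na(ang) & ang <= -180 + 1e-12] <- 180
  ang
}

.torsion_angles <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                     "chi", "P")

# atom quadruples per angle; offsets are residue-position shifts within the
# chain (0 = this residue)
.torsion_defs <- list(
  alpha   = list(atoms = c("O3'", "P", "O5'", "C5'"), off = c(-1, 0, 0, 0)),
  beta    = list(atoms = c("P", "O5'", "C5'", "C4'"), off = c(0, 0, 0, 0)),
  gamma   = list(atoms = c("O5'", "C5'", "C4'", "C3'"), off = c(0, 0, 0, 0)),
  delta   = list(atoms = c("C5'", "C4'", "C3'", "O3'"), off = c(0, 0, 0, 0)),
  epsilon = list(atoms = c("C4'", "C3'", "O3'", "P"), off = c(0, 0, 0, 1)),
  zeta    = list(atoms = c("C3'", "O3'", "P", "O5'"), off = c(0, 0, 1, 1))
)

.nu_defs <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'")
)

#' Backbone, glycosidic and pseudorotation torsion table
#'
#' Computes the seven dihedral angles alpha, beta, gamma, delta, epsilon,
#' zeta and chi plus the sugar pseudorotation phase P for every nucleotide.
#' An angle is defined iff all of its constituent atoms are present; the
#' 5'-terminal residue of a chain has no alpha, the 3'-terminal residue no
#' epsilon/zeta.  P (degrees in [0, 360)) is computed from the five
#' endocyclic torsions nu0-nu4 by
#' `tan P = ((nu4+nu1) - (nu3+nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' with the quadrant fixed by the sign of nu2.
#'
#' @param model An `rna_structure`.
#' @return An `rna_torsions` tibble, one row per residue and angle: `key`,
#'   `chain`, `resno`, `icode`, `base`, `angle`, `value` (degrees,
#'   (-180, 180] for dihedrals, [0, 360) for P) and `defined`.
#' @export
compute_torsions <- function(model) {
  stopifnot(inherits(model, "rna_structure"))
  res <- residues(model)
  atoms <- model$atoms
  lookup <- setNames(seq_len(nrow(atoms)), paste(atoms$key, atoms$atom))
  xyz <- coord_matrix(atoms)
  pos_in_chain <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)
  chain_len <- stats::ave(seq_len(nrow(res)), res$chain, FUN = length)

  coord_of <- function(res_idx, atom) {
    key <- ifelse(is.na(res_idx), NA, paste(res$key[res_idx], atom))
    idx <- lookup[key]
    out <- matrix(NA_real_, length(res_idx), 3)
    got <- !is.na(idx)
    out[got, ] <- xyz[idx[got], , drop = FALSE]
    out
  }
  neighbor <- function(shift) {
    if (shift == 0) return(seq_len(nrow(res)))
    tgt <- pos_in_chain + shift
    ok <- tgt >= 1 & tgt <= chain_len
    idx <- rep(NA_integer_, nrow(res))
    # residues are in chain order, so position shift = row shift within chain
    idx[ok] <- seq_len(nrow(res))[ok] + shift
    idx
  }

  rows <- list()
  for (ang in names(.torsion_defs)) {
    d <- .torsion_defs[[ang]]
    pts <- lapply(seq_len(4), function(i) {
      coord_of(neighbor(d$off[i]), d$atoms[i])
    })
    val <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    val[apply(sapply(pts, function(p) rowSums(is.na(p)) > 0), 1, any)] <- NA
    rows[[ang]] <- tibble(key = res$key, angle = ang, value = val)
  }
  # chi: purine O4'-C1'-N9-C4; pyrimidine O4'-C1'-N1-C2
  pur <- res$base %in% c("A", "G")
  n_atom <- ifelse(pur, "N9", "N1")
  l_atom <- ifelse(pur, "C4", "C2")
  p1 <- coord_of(seq_len(nrow(res)), "O4'")
  p2 <- coord_of(seq_len(nrow(res)), "C1'")
  p3 <- t(vapply(seq_len(nrow(res)), function(i) {
    coord_of(i, n_atom[i])[1, ]
  }, numeric(3)))
  p4 <- t(vapply(seq_len(nrow(res)), function(i) {
    coord_of(i, l_atom[i])[1, ]
  }, numeric(3)))
  chi <- dihedral_angle(p1, p2, p3, p4)
  chi[rowSums(is.na(p1)) > 0 | rowSums(is.na(p2)) > 0 |
        rowSums(is.na(p3)) > 0 | rowSums(is.na(p4)) > 0] <- NA
  rows[["chi"]] <- tibble(key = res$key, angle = "chi", value = chi)

  nu <- sapply(names(.nu_defs), function(nm) {
    a <- .nu_defs[[nm]]
    pts <- lapply(a, function(at) coord_of(seq_len(nrow(res)), at))
    v <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    v[apply(sapply(pts, function(p) rowSums(is.na(p)) > 0), 1, any)] <- NA
    v
  })
  nu <- matrix(nu, nrow = nrow(res),
               dimnames = list(NULL, names(.nu_defs)))
  num <- (nu[, "nu4"] + nu[, "nu1"]) - (nu[, "nu3"] + nu[, "nu0"])
  den <- 2 * nu[, "nu2"] * (sin(pi * 36 / 180) + sin(pi * 72 / 180))
  P <- atan(num / den) * 180 / pi
  P[!is.na(nu[, "nu2"]) & nu[, "nu2"] < 0] <-
    P[!is.na(nu[, "nu2"]) & nu[, "nu2"] < 0] + 180
  P <- P %% 360
  P[rowSums(is.na(nu)) > 0] <- NA
  rows[["P"]] <- tibble(key = res$key, angle = "P", value = P)

  out <- bind_rows(rows) %>%
    left_join(res %>% select("key", "chain", "resno", "icode", "base"),
              by = "key") %>%
    mutate(angle = factor(.data$angle, levels = .torsion_angles),
           defined = !is.na(.data$value)) %>%
    arrange(match(.data$key, res$key), .data$angle) %>%
    select("key", "chain", "resno", "icode", "base", "angle", "value",
           "defined")
  class(out) <- c("rna_torsions", class(out))
  out
}

#' Circular difference of two angles
#'
#' `min(|t1 - t2| mod 360, 360 - |t1 - t2| mod 360)`, in degrees in
#' [0, 180].  Vectorised.
#'
#' @param t1,t2 Angles in degrees.
#' @return Absolute circular differences.
#' @examples
#' circular_diff(350, 10)   # 20
#' circular_diff(0, 180)    # 180
#' @export
circular_diff <- function(t1, t2) {
  d <- abs(t1 - t2) %% 360
  pmin(d, 360 - d)
}

# align two torsion tables into comparable slots
torsion_slots <- function(reference, model, correspondence = NULL) {
  ref <- as_tibble(reference)[, c("key", "angle", "value")]
  mod <- as_tibble(model)[, c("key", "angle", "value")]
  if (!is.null(correspondence)) {
    map <- correspondence$pairs
    mod$key <- map$ref_key[match(mod$key, map$mod_key)]
    mod <- mod[!is.na(mod$key), ]
    ref <- ref[ref$key %in% map$ref_key, ]
  }
  full_join_slots <- dplyr::full_join(ref, mod, by = c("key", "angle"),
                                      suffix = c("_ref", "_mod"))
  full_join_slots
}

#' Mean of Circular Quantities between two torsion tables
#'
#' Over all angle slots defined in both tables, computes the circular
#' differences and aggregates them into a single dissimilarity in degrees in
#' [0, 180] ("MCQ-global").  The default aggregation is the circular mean
#' `atan2(mean sin, mean cos)` of the differences; an arithmetic mean is
#' available via `method = "arithmetic"`.  Slots defined on only one side
#' are excluded and counted, never imputed.  As a guide for large RNAs, a
#' global value below 15 degrees indicates high similarity and above 45
#' degrees overall dissimilarity.
#'
#' @param reference,model `rna_torsions` tables (see [compute_torsions()]).
#' @param correspondence Optional `rna_correspondence` used to align residue
#'   keys; when `NULL`, keys are matched directly.
#' @param method Aggregation of the per-slot differences.
#' @return An `rna_mcq`: list with `global_value` (degrees), `per_slot`
#'   tibble (`key`, `angle`, `diff`), `angles_compared` and `skipped`.
#' @export
mcq_global <- function(reference, model, correspondence = NULL,
                       method = c("circular", "arithmetic")) {
  method <- match.arg(method)
  slots <- torsion_slots(reference, model, correspondence)
  both <- !is.na(slots$value_ref) & !is.na(slots$value_mod)
  if (!any(both)) abort("no comparable torsion slots")
  dd <- circular_diff(slots$value_ref[both], slots$value_mod[both])
  gv <- if (method == "circular") {
    atan2(mean(sin(dd * pi / 180)), mean(cos(dd * pi / 180))) * 180 / pi
  } else {
    mean(dd)
  }
  structure(
    list(global_value = gv,
         per_slot = tibble(key = slots$key[both],
                           angle = slots$angle[both], diff = dd),
         angles_compared = sum(both),
         skipped = sum(xor(is.na(slots$value_ref), is.na(slots$value_mod))),
         method = method),
    class = "rna_mcq"
  )
}

#' Per-slot torsion differences (MCQ-local)
#'
#' Raw circular differences per residue and angle, with no averaging;
#' sensitive to single local distortions that a global score averages away.
#'
#' @inheritParams mcq_global
#' @return List with `diffs` (tibble `key`, `angle`, `diff`) and
#'   `skipped` (tibble of slots defined on one side only).
#' @export
mcq_local <- function(reference, model, correspondence = NULL) {
  slots <- torsion_slots(reference, model, correspondence)
  both <- !is.na(slots$value_ref) & !is.na(slots$value_mod)
  one <- xor(is.na(slots$value_ref), is.na(slots$value_mod))
  list(
    diffs = tibble(key = slots$key[both], angle = slots$angle[both],
                   diff = circular_diff(slots$value_ref[both],
                                        slots$value_mod[both])),
    skipped = tibble(key = slots$key[one], angle = slots$angle[one])
  )
}

#' @export
print.rna_mcq <- function(x, ...) {
  cat(sprintf("<rna_mcq> global = %.3f deg over %d angle slots (%d skipped)\n",
              x$global_value, x$angles_compared, x$skipped))
  invisible(x)
}

#' @method tidy rna_mcq
#' @export
tidy.rna_mcq <- function(x, ...) x$per_slot

#' @method glance rna_mcq
#' @export
glance.rna_mcq <- function(x, ...) {
  tibble(mcq = x$global_value, angles_compared = x$angles_compared,
         skipped = x$skipped, method = x$method)
}

#' Export a torsion table as CSV
#'
#' @param x An `rna_torsions` tibble.
#' @param path Output CSV path.
#' @return Invisibly, the exported data.
#' @export
write_torsions <- function(x, path) {
  out <- as_tibble(x)
  out$value <- round(out$value, 4)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(out)
}
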