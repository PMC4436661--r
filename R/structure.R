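#' RNA structure objects
#'
#' An `rna_structure` is a light container around a tidy atom table: one row
#' per atom with chain, residue number, insertion code, residue name, parent
#' base letter, atom name, element, orthogonal coordinates (Angstrom),
#' occupancy, B-factor and serial.  Residues are ordered by chain, then
#' (residue number, insertion code).
#'
#' @param atoms A tibble of atoms (see Details).
#' @param label Free-text model identifier.
#' @return An object of class `rna_structure`.
#' @details Required columns: `chain`, `resno`, `icode`, `resid`, `base`,
#'   `atom`, `elem`, `x`, `y`, `z`, `occ`, `b`, `serial`.  `base` is one of
#'   A/C/G/U or `NA` for retained non-nucleotide residues.
#' @export
new_rna_structure <- function(atoms, label = "model") {
  required <- c("chain", "resno", "icode", "resid", "base", "atom", "elem",
                "x", "y", "z", "occ", "b", "serial")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste("atom table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite atom coordinates")
  }
  if (anyDuplicated(atoms$serial)) abort("duplicate atom serials")
  structure(
    list(label = label, atoms = atoms),
    class = "rna_structure"
  )
}

#' Residue key strings
#'
#' Residues are identified throughout the package by `chain:number` keys
#' (with the insertion code appended as `^code` when present).
#'
#' @param chain,resno,icode Vectors of chain identifiers, residue numbers and
#'   insertion codes.
#' @return Character vector of keys.
#' @export
res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == "", "", paste0("^", icode))
  paste0(chain, ":", resno, icode)
}

#' @rdname res_key
#' @param x An `rna_structure`.
#' @return `res_keys()`: keys of all residues in structure order.
#' @export
res_keys <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  unique(x$atoms$key)
}

#' Residue-level summary of a structure
#'
#' @param x An `rna_structure`.
#' @return A tibble with one row per residue: key, chain, resno, icode,
#'   resid, base and atom count, in structure order.
#' @export
residues <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  x$atoms %>%
    group_by(.data$key) %>%
    summarise(
      chain = first(.data$chain), resno = first(.data$resno),
      icode = first(.data$icode), resid = first(.data$resid),
      base = first(.data$base), n_atoms = n(), .groups = "drop"
    ) %>%
    arrange(match(.data$key, unique(x$atoms$key)))
}

#' @export
print.rna_structure <- function(x, ...) {
  res <- residues(x)
  chains <- unique(res$chain)
  cat(sprintf("<rna_structure> '%s': %d chain(s), %d residues, %d atoms%s\n",
              x$label, length(chains), nrow(res), nrow(x$atoms),
              if (has_hydrogens(x)) " (with hydrogens)" else ""))
  for (ch in chains) {
    seq_ch <- paste(ifelse(is.na(res$base[res$chain == ch]), "x",
                           res$base[res$chain == ch]), collapse = "")
    if (nchar(seq_ch) > 60) seq_ch <- paste0(substr(seq_ch, 1, 57), "...")
    cat(sprintf("  chain %s: %s\n", ch, seq_ch))
  }
  invisible(x)
}

#' @rdname new_rna_structure
#' @param x An `rna_structure`.
#' @export
atom_count <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  nrow(x$atoms)
}

#' @rdname new_rna_structure
#' @export
has_hydrogens <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  any(x$atoms$elem == "H")
}

# coordinate matrix (n x 3) of an atom table
coord_matrix <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

# replace coordinates of a structure (same atom order)
set_coords <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Apply a rigid motion to a structure
#'
#' @param model An `rna_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed structure.
#' @export
transform_structure <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "rna_structure"))
  xyz <- coord_matrix(model$atoms) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(model, xyz)
}

# rotation matrix about an arbitrary axis (degrees)
rotation_about <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
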