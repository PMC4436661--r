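#' Matched atom coordinates for superposition
#'
#' For each residue pair of the correspondence, collects atoms with identical
#' names present on both sides and in the requested selection, in a
#' deterministic order (residue pair order, then atom name).
#'
#' @param reference,model `rna_structure` objects.
#' @param correspondence An `rna_correspondence`.
#' @param selection One of `"all-heavy"` (default), `"backbone"`,
#'   `"c1-prime"`, `"phosphate"`.
#' @return List with coordinate matrices `P` (reference) and `Q` (model) and
#'   a tibble `meta` (`ref_key`, `mod_key`, `atom`).
#' @export
paired_atoms <- function(reference, model, correspondence,
                         selection = "all-heavy") {
  stopifnot(inherits(correspondence, "rna_correspondence"))
  pr <- correspondence$pairs
  if (nrow(pr) == 0) abort("empty correspondence")
  ra <- selection_filter(reference$atoms, selection)
  ma <- selection_filter(model$atoms, selection)
  ra <- ra[ra$key %in% pr$ref_key, c("key", "atom", "x", "y", "z")]
  ma <- ma[ma$key %in% pr$mod_key, c("key", "atom", "x", "y", "z")]
  ra$pair <- match(ra$key, pr$ref_key)
  ma$pair <- match(ma$key, pr$mod_key)
  j <- inner_join(ra, ma, by = c("pair", "atom"), suffix = c("_r", "_m"),
                  relationship = "one-to-one")
  if (nrow(j) == 0) abort("zero common atoms under selection")
  j <- j %>% arrange(.data$pair, .data$atom)
  list(
    P = cbind(j$x_r, j$y_r, j$z_r),
    Q = cbind(j$x_m, j$y_m, j$z_m),
    meta = tibble(ref_key = j$key_r, mod_key = j$key_m, atom = j$atom)
  )
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid motion mapping point set `Q` onto `P`; reflections are
#' excluded (the rotation determinant is forced to +1).
#'
#' @param P,Q n x 3 coordinate matrices, n >= 3, not all collinear.
#' @return An `rna_superposition`: list with `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom) and `atom_pairs_used`.
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' s <- kabsch_superpose(P, P)
#' s$rmsd  # 0
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3) {
    abort("P and Q must be equal-size n x 3 matrices")
  }
  if (nrow(P) < 3) abort("degenerate point set: fewer than 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  for (M in list(Pc, Qc)) {
    sv <- svd(M, nu = 0, nv = 0)$d
    if (sv[2] <= 1e-8 * max(sv[1], 1e-12)) {
      abort("degenerate point set: collinear coordinates")
    }
  }
  M <- crossprod(Qc, Pc)            # maximise tr(R M)
  s <- svd(M)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pc - fit)^2)))
  structure(
    list(rotation = R, translation = as.numeric(cp - R %*% cq),
         rmsd = rmsd, atom_pairs_used = nrow(P)),
    class = "rna_superposition"
  )
}

#' RMSD between two structures
#'
#' Composes [paired_atoms()] and [kabsch_superpose()]: the global
#' least-squares RMSD over all paired atoms under the chosen selection.
#'
#' @inheritParams paired_atoms
#' @param correspondence An `rna_correspondence`; built with the default
#'   by-alignment mode when `NULL`.
#' @return An `rna_superposition` with fields `rmsd`, `rotation`,
#'   `translation`, `atom_pairs_used` and `selection`.
#' @export
rmsd_between <- function(reference, model, correspondence = NULL,
                         selection = "all-heavy") {
  if (is.null(correspondence)) {
    correspondence <- build_correspondence(reference, model)
  }
  pa <- paired_atoms(reference, model, correspondence, selection)
  sp <- kabsch_superpose(pa$P, pa$Q)
  sp$selection <- selection
  sp
}

#' @export
print.rna_superposition <- function(x, ...) {
  cat(sprintf("<rna_superposition> rmsd = %.4f A over %d atom pairs\n",
              x$rmsd, x$atom_pairs_used))
  invisible(x)
}

#' @method tidy rna_superposition
#' @export
tidy.rna_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, atom_pairs_used = x$atom_pairs_used,
         selection = x$selection %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
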