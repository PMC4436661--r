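# Geometric annotation of base pairs (Leontis-Westhof edges, cis/trans) and
# base stacking.  Thresholds follow common annotation practice and are
# collected in one place so they can be calibrated against a reference
# annotator.

.annot_params <- list(
  contact_max = 3.5,      # A, donor-acceptor heavy-atom contact
  contact_single = 3.2,   # A, sufficient on its own
  plane_angle_max = 65,   # deg, between base planes
  offset_max = 2.5,       # A, origin offset from partner plane
  origin_max = 12,        # A, base origin separation (pairs)
  stack_dist_max = 5.5,   # A, origin separation (stacking)
  stack_normal_max = 30,  # deg, between normals (folded)
  stack_vertical_max = 40 # deg, center-center vector vs either normal
)

#' Base reference frame of a residue
#'
#' Origin at the ring-atom centroid; z along the best-fit plane normal with a
#' chirality-fixed sign (via the glycosidic nitrogen and its ring neighbour),
#' x toward the glycosidic nitrogen.
#'
#' @param residue_atoms Atom tibble of one residue (rows of
#'   `rna_structure$atoms`).
#' @param base Parent base letter (A/C/G/U); defaults to the residue's
#'   `base` column.
#' @return List with `origin`, `x`, `y`, `z` (unit vectors) and `ok`;
#'   `ok = FALSE` flags an unannotatable residue (missing ring atoms).
#' @export
base_frame <- function(residue_atoms, base = residue_atoms$base[1]) {
  if (is.na(base) || !base %in% names(.ring_atoms)) {
    return(list(ok = FALSE))
  }
  ring <- .ring_atoms[[base]]
  idx <- match(ring, residue_atoms$atom)
  if (anyNA(idx)) return(list(ok = FALSE))
  rc <- coord_matrix(residue_atoms[idx, ])
  origin <- colMeans(rc)
  sv <- svd(sweep(rc, 2, origin))
  z <- sv$v[, 3]
  n_gly <- coord_matrix(residue_atoms[match(.glyco_n[[base]],
                                            residue_atoms$atom), ])[1, ]
  c_ref <- coord_matrix(residue_atoms[match(.chi_ref[[base]],
                                            residue_atoms$atom), ])[1, ]
  chir <- cross3(n_gly - origin, c_ref - origin)
  if (sum(z * chir) < 0) z <- -z
  xv <- n_gly - origin
  xv <- xv - sum(xv * z) * z
  xv <- xv / sqrt(sum(xv^2))
  list(origin = origin, x = xv, y = cross3(z, xv), z = z, ok = TRUE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# frames, origins and normals for all annotatable residues of a structure
structure_frames <- function(model) {
  res <- residues(model)
  by_res <- split(model$atoms, factor(model$atoms$key, levels = res$key))
  frames <- lapply(res$key, function(k) base_frame(by_res[[k]]))
  ok <- vapply(frames, function(f) isTRUE(f$ok), logical(1))
  list(res = res, frames = frames, ok = ok, atoms_by_res = by_res)
}

#' Detect base pairs
#'
#' A pair is emitted when the two bases are close and roughly coplanar and
#' their edges form at least one short donor-acceptor (N/O) contact: at
#' least two contacts within 3.5 A, or one within 3.2 A; inter-plane angle
#' <= 65 deg; each origin within 2.5 A of the partner plane; origin distance
#' <= 12 A.  The interacting edge (Watson-Crick / Hoogsteen / Sugar) on each
#' base is the edge contributing most contacts (ties: W > H > S); the
#' orientation is cis when the pseudo-dihedral C1'(i)-N(i)-N(j)-C1'(j) is
#' within +/-90 deg.  Consecutive residues of one chain are never reported
#' as base pairs.
#'
#' @param model An `rna_structure`.
#' @param wobble_as_wc Count the GU cis Watson-Crick/Watson-Crick wobble in
#'   the canonical category (the usual convention); set `FALSE` to restrict
#'   canonical to AU and GC.
#' @return Tibble of pairs: `res_i`, `res_j` (keys, i before j in structure
#'   order), `base_i`, `base_j`, `edge_i`, `edge_j`, `orientation` and
#'   `canonical_wc` (cis Watson-Crick/Watson-Crick AU, GC or GU).
#' @export
detect_base_pairs <- function(model, wobble_as_wc = TRUE) {
  sf <- structure_frames(model)
  detect_base_pairs_impl(sf, wobble_as_wc)
}

detect_base_pairs_impl <- function(sf, wobble_as_wc = TRUE) {
  p <- .annot_params
  res <- sf$res
  empty <- tibble(res_i = character(0), res_j = character(0),
                  base_i = character(0), base_j = character(0),
                  edge_i = character(0), edge_j = character(0),
                  orientation = character(0), canonical_wc = logical(0))
  idx <- which(sf$ok)
  if (length(idx) < 2) return(empty)
  origins <- t(vapply(sf$frames[idx], function(f) f$origin, numeric(3)))
  dmat <- as.matrix(stats::dist(origins))
  cand <- which(upper.tri(dmat) & dmat <= p$origin_max, arr.ind = TRUE)
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- idx[cand[r, 1]]; j <- idx[cand[r, 2]]
    # chain neighbours are stacking candidates only
    if (res$chain[i] == res$chain[j] && abs(i - j) == 1) next
    fi <- sf$frames[[i]]; fj <- sf$frames[[j]]
    ang <- acosd(min(1, abs(sum(fi$z * fj$z))))
    if (ang > p$plane_angle_max) next
    dvec <- fj$origin - fi$origin
    if (abs(sum(dvec * fi$z)) > p$offset_max) next
    if (abs(sum(dvec * fj$z)) > p$offset_max) next
    ai <- sf$atoms_by_res[[res$key[i]]]
    aj <- sf$atoms_by_res[[res$key[j]]]
    ei <- .edge_atoms[[res$base[i]]]
    ej <- .edge_atoms[[res$base[j]]]
    pol_i <- ai[ai$atom %in% unique(unlist(ei)), ]
    pol_j <- aj[aj$atom %in% unique(unlist(ej)), ]
    if (nrow(pol_i) == 0 || nrow(pol_j) == 0) next
    dd <- outer_dist(coord_matrix(pol_i), coord_matrix(pol_j))
    hits <- which(dd <= p$contact_max, arr.ind = TRUE)
    if (nrow(hits) == 0) next
    if (nrow(hits) < 2 && min(dd) > p$contact_single) next
    edge_i <- pick_edge(ei, pol_i$atom[hits[, 1]])
    edge_j <- pick_edge(ej, pol_j$atom[hits[, 2]])
    orientation <- pair_orientation(ai, aj, res$base[i], res$base[j])
    if (is.na(orientation)) next
    combo <- paste(sort(c(res$base[i], res$base[j])), collapse = "")
    canonical_combos <- c("AU", "CG", if (wobble_as_wc) "GU")
    canonical <- orientation == "cis" && edge_i == "W" && edge_j == "W" &&
      combo %in% canonical_combos
    out[[length(out) + 1]] <- tibble(
      res_i = res$key[i], res_j = res$key[j],
      base_i = res$base[i], base_j = res$base[j],
      edge_i = edge_i, edge_j = edge_j,
      orientation = orientation, canonical_wc = canonical)
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

acosd <- function(x) acos(pmin(1, pmax(-1, x))) * 180 / pi

outer_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

# most-contacted edge; ties resolve W > H > S
pick_edge <- function(edge_sets, contact_atoms) {
  counts <- vapply(c("W", "H", "S"), function(e) {
    sum(contact_atoms %in% edge_sets[[e]])
  }, numeric(1))
  c("W", "H", "S")[which.max(counts)]
}

pair_orientation <- function(ai, aj, base_i, base_j) {
  pts <- list(
    ai[match("C1'", ai$atom), ], ai[match(.glyco_n[[base_i]], ai$atom), ],
    aj[match(.glyco_n[[base_j]], aj$atom), ], aj[match("C1'", aj$atom), ])
  if (any(vapply(pts, function(x) anyNA(x$x), logical(1)))) return(NA_character_)
  d <- dihedral_angle(coord_matrix(pts[[1]]), coord_matrix(pts[[2]]),
                      coord_matrix(pts[[3]]), coord_matrix(pts[[4]]))
  if (is.na(d)) return(NA_character_)
  if (abs(d) <= 90) "cis" else "trans"
}

#' Detect base stacking contacts
#'
#' A stacking contact is emitted when base origins are within 5.5 A, the
#' base normals are within 30 deg of (anti)parallel, and the center-center
#' vector is within 40 deg of either normal.  Residue pairs already emitted
#' as base pairs are excluded.
#'
#' @param model An `rna_structure`.
#' @param pairs Optional precomputed base-pair tibble (from
#'   [detect_base_pairs()]); recomputed when `NULL`.
#' @return Tibble of contacts: `res_i`, `res_j` (keys, structure order).
#' @export
detect_stacking <- function(model, pairs = NULL) {
  sf <- structure_frames(model)
  if (is.null(pairs)) pairs <- detect_base_pairs_impl(sf)
  detect_stacking_impl(sf, pairs)
}

detect_stacking_impl <- function(sf, pairs) {
  p <- .annot_params
  res <- sf$res
  empty <- tibble(res_i = character(0), res_j = character(0))
  idx <- which(sf$ok)
  if (length(idx) < 2) return(empty)
  origins <- t(vapply(sf$frames[idx], function(f) f$origin, numeric(3)))
  dmat <- as.matrix(stats::dist(origins))
  cand <- which(upper.tri(dmat) & dmat <= p$stack_dist_max, arr.ind = TRUE)
  paired <- paste(pairs$res_i, pairs$res_j)
  out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- idx[cand[r, 1]]; j <- idx[cand[r, 2]]
    if (paste(res$key[i], res$key[j]) %in% paired) next
    fi <- sf$frames[[i]]; fj <- sf$frames[[j]]
    if (acosd(abs(sum(fi$z * fj$z))) > p$stack_normal_max) next
    dvec <- fj$origin - fi$origin
    dvec <- dvec / sqrt(sum(dvec^2))
    vert <- min(acosd(abs(sum(dvec * fi$z))), acosd(abs(sum(dvec * fj$z))))
    if (vert > p$stack_vertical_max) next
    out[[length(out) + 1]] <- tibble(res_i = res$key[i], res_j = res$key[j])
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Full interaction set of a structure
#'
#' Aggregates [detect_base_pairs()] and [detect_stacking()] with
#' deterministic ordering.
#'
#' @param model An `rna_structure`.
#' @inheritParams detect_base_pairs
#' @return An `rna_interactions`: list with `pairs`, `stacks`,
#'   `skipped` (keys of unannotatable residues) and `source_label`.
#' @export
interactions_of <- function(model, wobble_as_wc = TRUE) {
  sf <- structure_frames(model)
  pairs <- detect_base_pairs_impl(sf, wobble_as_wc)
  stacks <- detect_stacking_impl(sf, pairs)
  key_order <- sf$res$key
  pairs <- pairs %>% arrange(match(.data$res_i, key_order),
                             match(.data$res_j, key_order))
  stacks <- stacks %>% arrange(match(.data$res_i, key_order),
                               match(.data$res_j, key_order))
  structure(
    list(pairs = pairs, stacks = stacks,
         skipped = sf$res$key[!sf$ok], source_label = model$label),
    class = "rna_interactions"
  )
}

#' @export
print.rna_interactions <- function(x, ...) {
  cat(sprintf("<rna_interactions> '%s': %d base pairs (%d canonical WC), %d stacking contacts\n",
              x$source_label, nrow(x$pairs), sum(x$pairs$canonical_wc),
              nrow(x$stacks)))
  if (length(x$skipped) > 0) {
    cat(sprintf("  %d unannotatable residue(s)\n", length(x$skipped)))
  }
  invisible(x)
}

#' @method tidy rna_interactions
#' @export
tidy.rna_interactions <- function(x, ...) {
  bp <- x$pairs %>%
    mutate(type = ifelse(.data$canonical_wc, "wc_pair", "nwc_pair")) %>%
    select("res_i", "res_j", "type", "edge_i", "edge_j", "orientation")
  st <- x$stacks %>%
    mutate(type = "stacking", edge_i = NA_character_,
           edge_j = NA_character_, orientation = NA_character_) %>%
    select("res_i", "res_j", "type", "edge_i", "edge_j", "orientation")
  bind_rows(bp, st)
}

#' Export an interaction set as CSV
#'
#' @param x An `rna_interactions`.
#' @param path Output CSV path.
#' @return Invisibly, the exported tibble.
#' @export
write_interactions <- function(x, path) {
  out <- tidy(x)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(out)
}
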