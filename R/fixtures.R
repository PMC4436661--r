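# Synthetic decoy generator: ideal A-form helices and controlled
# perturbations with known ground-truth metric values.

# helical placement parameters (frozen with the versioned templates in
# inst/extdata/aform-templates.pdb): standard A-form fiber twist/rise; the
# x-displacement and inclination were fixed once, together with the template
# sugar pose, so that the backbone closes (O3'-P ~1.6 A) clash-free
.helix_params <- list(
  twist = 32.7,       # degrees per step
  rise = 2.81,        # Angstrom per step
  x_disp = -4.5900,   # Angstrom, pair frame -> helix axis
  inclination = 25.9697  # degrees about x
)

the_template_env <- new.env(parent = emptyenv())

aform_templates <- function() {
  if (is.null(the_template_env$tpl)) {
    path <- system.file("extdata", "aform-templates.pdb",
                        package = "rnassess", mustWork = TRUE)
    tpl <- read_pdb(path, label = "aform-templates")
    the_template_env$tpl <- split(tpl$atoms, tpl$atoms$resid)
  }
  the_template_env$tpl
}

# pair-frame -> global coordinates for pair step k (0-based); strand two is
# the 180-degree rotation about x (flip = TRUE) before placement
helix_place <- function(xyz, k, flip = FALSE) {
  p <- .helix_params
  if (flip) xyz <- xyz %*% diag(c(1, -1, -1))
  xyz <- xyz %*% t(rotation_about(c(1, 0, 0), p$inclination))
  xyz[, 1] <- xyz[, 1] + p$x_disp
  xyz <- xyz %*% t(rotation_about(c(0, 0, 1), k * p$twist))
  xyz[, 3] <- xyz[, 3] + k * p$rise
  xyz
}

#' Build an ideal A-form helix
#'
#' Generates an ideal A-form duplex (the given strand plus its reverse
#' complement, chains A and B) or a single strand, from per-nucleotide
#' template coordinates by helical symmetry (twist 32.7 degrees, rise
#' 2.81 Angstrom per step).  The duplex annotates with exactly one canonical
#' Watson-Crick pair per position and stacked neighbours, and its backbone
#' is covalently continuous -- a fully characterised reference for testing
#' assessment metrics.
#'
#' @param sequence Strand sequence, 5'->3', letters A/C/G/U.
#' @param single_strand Build only the given strand.
#' @param label Model label.
#' @return An `rna_structure`.
#' @examples
#' h <- build_helix("GGGG")
#' interactions_of(h)
#' @export
build_helix <- function(sequence, single_strand = FALSE,
                        label = paste0("helix-", sequence)) {
  letters_ <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters_) == 0) abort("empty sequence")
  bad <- setdiff(letters_, c("A", "C", "G", "U"))
  if (length(bad) > 0) {
    abort(paste0("sequence letters must be A/C/G/U; found: ",
                 paste(unique(bad), collapse = ", ")))
  }
  tpl <- aform_templates()
  n <- length(letters_)

  place_residue <- function(base, k, flip, chain, resno) {
    t0 <- tpl[[base]]
    xyz <- helix_place(coord_matrix(t0), k, flip)
    tibble(chain = chain, resno = resno, icode = "", resid = base,
           base = base, atom = t0$atom, elem = t0$elem,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
           serial = 0L)
  }
  rows <- lapply(seq_len(n), function(k) {
    place_residue(letters_[k], k - 1, FALSE, "A", k)
  })
  if (!single_strand) {
    comp <- .rna_complement[letters_]
    rows <- c(rows, lapply(seq_len(n), function(j) {
      k <- n - j + 1  # chain B runs 5'->3' against the pair steps
      place_residue(comp[[k]], k - 1, TRUE, "B", j)
    }))
  }
  atoms <- bind_rows(rows)
  atoms$serial <- seq_len(nrow(atoms))
  new_rna_structure(atoms, label = label)
}

#' Minimal backbone-trace model from a sequence
#'
#' Builds a synthetic single-chain model with one C1' atom per nucleotide at
#' spaced positions.  Useful for sequence-level checks (chain lengths,
#' correspondence) where full coordinates are irrelevant.
#'
#' @param sequence Nucleotide string (A/C/G/U).
#' @param chain Chain identifier.
#' @param label Model label.
#' @return An `rna_structure` with one atom per residue.
#' @export
trace_model <- function(sequence, chain = "A", label = "trace") {
  letters_ <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters_) == 0) abort("empty sequence")
  bad <- setdiff(letters_, c("A", "C", "G", "U"))
  if (length(bad) > 0) {
    abort(paste0("sequence letters must be A/C/G/U; found: ",
                 paste(unique(bad), collapse = ", ")))
  }
  n <- length(letters_)
  atoms <- tibble(
    chain = chain, resno = seq_len(n), icode = "", resid = letters_,
    base = letters_, atom = "C1'", elem = "C",
    x = 6 * seq_len(n), y = 0, z = 0, occ = 1, b = 0, serial = seq_len(n)
  )
  new_rna_structure(atoms, label = label)
}

#' Perturbation specifications
#'
#' Constructors for the three decoy perturbation kinds applied by
#' [perturb()]:
#' \describe{
#'   \item{`perturb_noise(sigma, seed)`}{i.i.d. zero-mean Gaussian
#'     displacement of standard deviation `sigma` (Angstrom) per coordinate;
#'     a fixed `seed` makes the decoy bit-stable.}
#'   \item{`perturb_rigid(chain, start, end, angle, axis_point, axis_dir,
#'     translation)`}{rigid rotation (degrees) plus optional translation of
#'     one residue range only, emulating a mis-placed domain.}
#'   \item{`perturb_bond(key, bond, delta)`}{rotation of all atoms distal to
#'     a named rotatable bond by `delta` degrees about the bond axis,
#'     changing exactly that torsion by `delta`.  `bond` is a torsion name
#'     (`"chi"`, `"alpha"`, `"beta"`, `"gamma"`, `"epsilon"`, `"zeta"`) or a
#'     length-2 vector of atom names.}
#' }
#'
#' @param sigma Noise standard deviation per coordinate (Angstrom).
#' @param seed Optional integer seed (noise only).
#' @param chain,start,end Residue range of the rigid domain.
#' @param angle Rotation angle, degrees.
#' @param axis_point Point on the rotation axis (default: domain centroid).
#' @param axis_dir Axis direction (default z).
#' @param translation Optional translation, Angstrom.
#' @param key Residue key (`"A:3"`) owning the rotated bond.
#' @param bond Torsion name or atom-name pair.
#' @param delta Torsion change, degrees.
#' @return A perturbation spec for [perturb()].
#' @name perturbations
NULL

#' @rdname perturbations
#' @export
perturb_noise <- function(sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  structure(list(kind = "noise", sigma = sigma, seed = seed),
            class = "rna_perturbation")
}

#' @rdname perturbations
#' @export
perturb_rigid <- function(chain, start, end, angle, axis_point = NULL,
                          axis_dir = c(0, 0, 1), translation = c(0, 0, 0)) {
  structure(list(kind = "rigid-domain", chain = chain, start = start,
                 end = end, angle = angle, axis_point = axis_point,
                 axis_dir = axis_dir, translation = translation),
            class = "rna_perturbation")
}

#' @rdname perturbations
#' @export
perturb_bond <- function(key, bond, delta) {
  structure(list(kind = "bond-rotation", key = key, bond = bond,
                 delta = delta),
            class = "rna_perturbation")
}

#' Apply a perturbation to a structure
#'
#' @param model An `rna_structure`.
#' @param spec A spec from [perturb_noise()], [perturb_rigid()] or
#'   [perturb_bond()].
#' @return The perturbed `rna_structure` (label suffixed with the kind).
#' @export
perturb <- function(model, spec) {
  stopifnot(inherits(model, "rna_structure"),
            inherits(spec, "rna_perturbation"))
  out <- switch(spec$kind,
    "noise" = perturb_noise_impl(model, spec),
    "rigid-domain" = perturb_rigid_impl(model, spec),
    "bond-rotation" = perturb_bond_impl(model, spec)
  )
  out$label <- paste0(model$label, "+", spec$kind)
  out
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

perturb_noise_impl <- function(model, spec) {
  n <- atom_count(model)
  noise <- with_local_seed(spec$seed,
                           matrix(rnorm(3 * n, sd = spec$sigma), n, 3))
  if (spec$sigma == 0) noise[] <- 0
  set_coords(model, coord_matrix(model$atoms) + noise)
}

perturb_rigid_impl <- function(model, spec) {
  atoms <- model$atoms
  sel <- atoms$chain == spec$chain & atoms$resno >= spec$start &
    atoms$resno <= spec$end
  if (!any(sel)) abort("rigid-domain residue range selects no atoms")
  xyz <- coord_matrix(atoms)
  pivot <- spec$axis_point %||% colMeans(xyz[sel, , drop = FALSE])
  R <- rotation_about(spec$axis_dir, spec$angle)
  moved <- sweep(xyz[sel, , drop = FALSE], 2, pivot) %*% t(R)
  moved <- sweep(moved, 2, pivot + spec$translation, "+")
  xyz[sel, ] <- moved
  set_coords(model, xyz)
}

# torsion name -> (axis atom 1, axis atom 2); the rotated side is the
# connected component holding atom 2 after cutting the bond
.rotatable_bonds <- list(
  alpha = c("P", "O5'"), beta = c("O5'", "C5'"), gamma = c("C5'", "C4'"),
  epsilon = c("C3'", "O3'"), zeta = c("O3'", "P+1"), chi = c("C1'", "N")
)

perturb_bond_impl <- function(model, spec) {
  atoms <- model$atoms
  res <- residues(model)
  k <- match(spec$key, res$key)
  if (is.na(k)) abort(paste0("no residue with key ", spec$key))
  base <- res$base[k]
  bond <- spec$bond
  if (length(bond) == 1) {
    if (!bond %in% names(.rotatable_bonds)) {
      abort(paste0("unknown bond name '", bond,
                   "' (delta is ring-internal and not rotatable)"))
    }
    bond <- .rotatable_bonds[[bond]]
    bond[bond == "N"] <- .glyco_n[[base]]
  }
  resolve <- function(nm) {
    if (nm == "P+1") {
      if (k == nrow(res) || res$chain[k + 1] != res$chain[k]) {
        abort("bond crosses a chain end")
      }
      return(which(atoms$key == res$key[k + 1] & atoms$atom == "P"))
    }
    which(atoms$key == spec$key & atoms$atom == nm)
  }
  i1 <- resolve(bond[1]); i2 <- resolve(bond[2])
  if (length(i1) != 1 || length(i2) != 1) {
    abort(paste0("bond atoms not found: ", paste(bond, collapse = "-")))
  }
  adj <- chain_bond_adjacency(model)
  # cut the bond, flood from atom 2
  adj[[i1]] <- setdiff(adj[[i1]], i2)
  adj[[i2]] <- setdiff(adj[[i2]], i1)
  comp <- flood_from(adj, i2)
  if (i1 %in% comp) abort("bond not rotatable (part of a ring)")
  xyz <- coord_matrix(atoms)
  # rotating the atom-2-side component about the atom1->atom2 axis by +delta
  # increases the a-b-c-d torsion through this bond by +delta (IUPAC sign)
  axis <- xyz[i2, ] - xyz[i1, ]
  R <- rotation_about(axis, spec$delta)
  moved <- sweep(xyz[comp, , drop = FALSE], 2, xyz[i1, ]) %*% t(R)
  xyz[comp, ] <- sweep(moved, 2, xyz[i1, ], "+")
  set_coords(model, xyz)
}

chain_bond_adjacency <- function(model) {
  atoms <- model$atoms
  n <- nrow(atoms)
  idx <- setNames(seq_len(n), paste(atoms$key, atoms$atom))
  res <- residues(model)
  edges <- list()
  for (k in seq_len(nrow(res))) {
    b <- residue_bonds(res$base[k])
    i1 <- idx[paste(res$key[k], b[, 1])]
    i2 <- idx[paste(res$key[k], b[, 2])]
    ok <- !is.na(i1) & !is.na(i2)
    edges[[length(edges) + 1]] <- cbind(i1[ok], i2[ok])
  }
  for (k in seq_len(nrow(res) - 1)) {
    if (res$chain[k] != res$chain[k + 1]) next
    o3 <- idx[paste(res$key[k], "O3'")]
    p <- idx[paste(res$key[k + 1], "P")]
    if (!is.na(o3) && !is.na(p)) {
      edges[[length(edges) + 1]] <- cbind(o3, p)
    }
  }
  em <- do.call(rbind, edges)
  adj <- vector("list", n)
  for (r in seq_len(nrow(em))) {
    adj[[em[r, 1]]] <- c(adj[[em[r, 1]]], em[r, 2])
    adj[[em[r, 2]]] <- c(adj[[em[r, 2]]], em[r, 1])
  }
  adj
}

flood_from <- function(adj, start) {
  seen <- rep(FALSE, length(adj))
  queue <- start
  seen[start] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    nxt <- adj[[cur]]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  which(seen)
}

#' Graded decoy suite with analytic expectations
#'
#' Builds an ideal duplex for `sequence` and emits a graded series of
#' decoys: Gaussian coordinate noise at increasing `sigma` (expected RMSD
#' `sigma * sqrt(3)` for large atom counts) and rigid rotations of the
#' second half of chain A at increasing angle.  The attached expectations
#' make the suite a self-checking test substrate.
#'
#' @param sequence Duplex strand sequence.
#' @param seeds Integer seeds; one decoy per (seed, parameter).
#' @param sigmas Noise levels, Angstrom.
#' @param angles Rigid-domain rotation angles, degrees.
#' @return Tibble: `kind`, `param`, `seed`, `model` (list column),
#'   `expected_rmsd` (`NA` where no closed form applies).
#' @export
decoy_suite <- function(sequence, seeds = 1:3, sigmas = c(0.1, 0.5, 1.0),
                        angles = c(10, 30, 60)) {
  ref <- build_helix(sequence)
  rows <- list()
  for (s in sigmas) {
    for (sd_ in seeds) {
      rows[[length(rows) + 1]] <- tibble(
        kind = "noise", param = s, seed = sd_,
        model = list(perturb(ref, perturb_noise(s, seed = sd_))),
        expected_rmsd = s * sqrt(3))
    }
  }
  n <- nchar(sequence)
  half <- (n %/% 2 + 1)
  for (a in angles) {
    rows[[length(rows) + 1]] <- tibble(
      kind = "rigid-domain", param = a, seed = NA_integer_,
      model = list(perturb(ref, perturb_rigid("A", half, n, a))),
      expected_rmsd = NA_real_)
  }
  out <- bind_rows(rows)
  attr(out, "reference") <- ref
  out
}

#' Write a decoy suite ledger as JSON
#'
#' @param suite Output of [decoy_suite()].
#' @param path Output JSON path.
#' @return Invisibly, the ledger list.
#' @export
write_decoy_ledger <- function(suite, path) {
  led <- lapply(seq_len(nrow(suite)), function(i) {
    list(kind = suite$kind[i], param = suite$param[i],
         seed = suite$seed[i], label = suite$model[[i]]$label,
         expected_rmsd = suite$expected_rmsd[i])
  })
  jsonlite::write_json(led, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(led)
}
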