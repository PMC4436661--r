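#' Read an RNA structure from PDB-format text
#'
#' Parses ATOM/HETATM records into an [new_rna_structure()] object.  By
#' default only nucleotide residues are retained: standard A/C/G/U residues
#' and modified nucleotides with a known parent base (HETATM or ATOM).
#' Waters and single-atom ion records are always dropped; other ligands are
#' dropped unless `keep_ligands = TRUE`.  Alternate locations are resolved to
#' the highest occupancy (ties to the first encountered) and only one MODEL
#' block is read.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @param model Index of the MODEL block to read (default 1, i.e. the first).
#' @param keep_ligands Retain multi-atom non-nucleotide residues (with
#'   `base = NA`); they are ignored by annotation and torsion analysis.
#' @param modified_map Named character vector extending the built-in
#'   modified-nucleotide table, e.g. `c(XYZ = "G")`.
#' @param label Model label; defaults to the file name or "model".
#' @return An `rna_structure`.
#' @details Residues that look like nucleotides (sugar atoms plus a
#'   glycosidic nitrogen) but have an unknown residue code raise an error
#'   rather than being silently dropped; extend `modified_map` to accept
#'   them.  Old-style atom names (`O3*`, `O1P`) are normalised to the primed
#'   convention (`O3'`, `OP1`).
#' @export
read_pdb <- function(source, model = 1L, keep_ligands = FALSE,
                     modified_map = NULL, label = NULL) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(label)) label <- sub("\\.(pdb|ent)$", "", basename(source))
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(label)) label <- "model"
  }
  rec <- substr(lines, 1, 6)

  # MODEL block selection: if MODEL records exist, keep only the requested one
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 0) {
    if (model > length(model_starts)) {
      abort(sprintf("requested MODEL %d but file has %d", model,
                    length(model_starts)))
    }
    start <- model_starts[model]
    ends <- which(trimws(rec) == "ENDMDL")
    end <- ends[ends > start][1]
    if (is.na(end)) end <- length(lines)
    keep <- seq(start, end)
  } else {
    keep <- seq_along(lines)
  }

  is_atom <- keep[rec[keep] %in% c("ATOM  ", "HETATM")]
  if (length(is_atom) == 0) abort("no RNA content: no ATOM/HETATM records")
  atom_lines <- lines[is_atom]

  bad <- which(nchar(atom_lines) < 54)
  if (length(bad) > 0) {
    abort(sprintf("unparseable record at line %d: too short", is_atom[bad[1]]))
  }
  num_field <- function(from, to, default = NA_real_) {
    s <- trimws(substr(atom_lines, from, to))
    v <- suppressWarnings(as.numeric(s))
    v[s == ""] <- default
    v
  }
  x <- num_field(31, 38); y <- num_field(39, 46); z <- num_field(47, 54)
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    abort(sprintf("unparseable record at line %d: bad coordinates",
                  is_atom[bad[1]]))
  }
  serial <- num_field(7, 11)
  occ <- num_field(55, 60, default = 1)
  occ[is.na(occ)] <- 1
  bfac <- num_field(61, 66, default = 0)
  bfac[is.na(bfac)] <- 0

  name <- trimws(substr(atom_lines, 13, 16))
  # normalise old-style naming
  name <- gsub("*", "'", name, fixed = TRUE)
  name[name == "O1P"] <- "OP1"
  name[name == "O2P"] <- "OP2"
  name[name == "O3P"] <- "OP3"
  alt <- substr(atom_lines, 17, 17)
  resid <- trimws(substr(atom_lines, 18, 20))
  chain <- substr(atom_lines, 22, 22)
  resno <- suppressWarnings(as.integer(trimws(substr(atom_lines, 23, 26))))
  bad <- which(is.na(resno))
  if (length(bad) > 0) {
    abort(sprintf("unparseable record at line %d: bad residue number",
                  is_atom[bad[1]]))
  }
  icode <- trimws(substr(atom_lines, 27, 27))
  elem <- trimws(substr(atom_lines, 77, 78))
  guess <- toupper(substr(gsub("[0-9']", "", name), 1, 1))
  elem <- ifelse(elem == "", guess, toupper(elem))

  atoms <- tibble(
    chain = chain, resno = resno, icode = icode, resid = resid,
    atom = name, alt = alt, elem = elem, x = x, y = y, z = z,
    occ = occ, b = bfac, serial = as.integer(serial), ord = seq_along(x)
  )

  # alternate locations: highest occupancy wins, ties to first encountered
  atoms <- atoms %>%
    group_by(.data$chain, .data$resno, .data$icode, .data$atom) %>%
    arrange(desc(.data$occ), .data$ord, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$ord)

  # residue classification
  base_map <- c(setNames(c("A", "C", "G", "U"), c("A", "C", "G", "U")),
                .modified_bases, modified_map)
  res_tbl <- atoms %>%
    group_by(.data$chain, .data$resno, .data$icode, .data$resid) %>%
    summarise(n_heavy = sum(.data$elem != "H"),
              nucleotide_like = any(.data$atom == "C1'") &&
                any(.data$atom %in% c("N9", "N1")) &&
                sum(.data$atom %in% .backbone_atoms) >= 3,
              .groups = "drop")
  res_tbl$base <- unname(base_map[res_tbl$resid])
  unknown_nt <- res_tbl$resid[is.na(res_tbl$base) & res_tbl$nucleotide_like]
  if (length(unknown_nt) > 0) {
    abort(paste0("unknown nucleotide code(s): ",
                 paste(unique(unknown_nt), collapse = ", "),
                 "; extend `modified_map` to map them to a parent base"))
  }
  res_tbl$keep <- !is.na(res_tbl$base)
  if (keep_ligands) {
    res_tbl$keep <- res_tbl$keep |
      (!res_tbl$resid %in% .water_names & res_tbl$n_heavy > 1)
  }

  atoms <- atoms %>%
    left_join(res_tbl %>% select("chain", "resno", "icode", "resid",
                                 "base", "keep"),
              by = c("chain", "resno", "icode", "resid")) %>%
    filter(.data$keep)

  if (sum(!is.na(atoms$base)) == 0) abort("no RNA content")

  # order: chains in order of first appearance, residues by (number, icode)
  chain_order <- unique(atoms$chain)
  atoms <- atoms %>%
    arrange(match(.data$chain, chain_order), .data$resno, .data$icode,
            .data$ord) %>%
    select("chain", "resno", "icode", "resid", "base", "atom", "elem",
           "x", "y", "z", "occ", "b", "serial")

  new_rna_structure(atoms, label = label)
}
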