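#' Write a structure as PDB-format text
#'
#' Emits standard fixed-width ATOM records with fresh 1-based serials, a TER
#' record after each chain and a final END.  Coordinates are written at 3
#' decimal places, so `read_pdb(write_pdb(m))` reproduces coordinates to
#' that precision.
#'
#' @param model An `rna_structure`.
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(model, path = NULL) {
  stopifnot(inherits(model, "rna_structure"))
  atoms <- model$atoms
  if (nrow(atoms) == 0) abort("cannot write an empty model")
  if (any(nchar(atoms$atom) > 4)) {
    abort(paste0("atom name too long for PDB format: ",
                 atoms$atom[which(nchar(atoms$atom) > 4)[1]]))
  }
  name_field <- ifelse(nchar(atoms$atom) < 4,
                       sprintf(" %-3s", atoms$atom),
                       atoms$atom)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    idx <- which(atoms$chain == ch)
    rows <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial + seq_along(idx), name_field[idx],
      substr(atoms$resid[idx], 1, 3), ch, atoms$resno[idx],
      ifelse(atoms$icode[idx] == "", " ", atoms$icode[idx]),
      atoms$x[idx], atoms$y[idx], atoms$z[idx],
      atoms$occ[idx], atoms$b[idx], atoms$elem[idx])
    serial <- serial + length(idx)
    last <- idx[length(idx)]
    ter <- sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                   substr(atoms$resid[last], 1, 3), ch, atoms$resno[last])
    serial <- serial + 1L
    lines <- c(lines, rows, ter)
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Extract per-chain nucleotide sequences
#'
#' @param model An `rna_structure`.
#' @return Named character vector, one sequence per chain (modified bases as
#'   their parent letter).  Errors if a retained residue has no parent base.
#' @export
extract_sequence <- function(model) {
  stopifnot(inherits(model, "rna_structure"))
  res <- residues(model)
  if (nrow(res) == 0) return(setNames(character(0), character(0)))
  bad <- unique(res$resid[is.na(res$base)])
  if (length(bad) > 0) {
    abort(paste0("residue code(s) not mappable to a base: ",
                 paste(bad, collapse = ", ")))
  }
  out <- vapply(split(res$base, factor(res$chain, levels = unique(res$chain))),
                paste, character(1), collapse = "")
  out
}

#' Write chain sequences as FASTA
#'
#' @param model An `rna_structure`.
#' @param path Output FASTA path.
#' @return Invisibly, the sequences written.
#' @export
write_fasta <- function(model, path) {
  seqs <- extract_sequence(model)
  set <- Biostrings::RNAStringSet(seqs)
  names(set) <- paste0(model$label, "|", names(seqs))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(seqs)
}
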