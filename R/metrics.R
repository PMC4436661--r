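#' Compare interaction networks: TP/FP/FN per category
#'
#' Matches the model's annotated interactions against the reference's
#' through the residue correspondence.  An interaction matches when its
#' mapped residue pair agrees; base pairs are categorised as canonical
#' Watson-Crick (`wc`) vs non-Watson-Crick (`nwc`) using the reference
#' annotation for matches (the model's own annotation for false positives),
#' and stacking contacts form their own category.  With `strict = TRUE` a
#' base-pair match additionally requires identical edges and orientation.
#' Interactions that involve residues absent from the correspondence count
#' as false positives (model side) or false negatives (reference side).
#'
#' @param reference_set,model_set `rna_interactions` objects.
#' @param correspondence An `rna_correspondence`.
#' @param strict Require edge/orientation identity for base-pair matches.
#' @return Tibble with columns `category` (`wc`, `nwc`, `stack`, `all`) and
#'   counts `tp`, `fp`, `fn`.
#' @export
match_interactions <- function(reference_set, model_set, correspondence,
                               strict = FALSE) {
  stopifnot(inherits(reference_set, "rna_interactions"),
            inherits(model_set, "rna_interactions"),
            inherits(correspondence, "rna_correspondence"))
  map <- correspondence$pairs

  pair_id <- function(k1, k2, extra = NULL) {
    a <- pmin(k1, k2); b <- pmax(k1, k2)
    if (is.null(extra)) paste(a, b) else paste(a, b, extra)
  }
  # reference base pairs keep their own keys
  rp <- reference_set$pairs
  mp <- model_set$pairs
  # map model keys into reference key space (NA if unmatched)
  mp_i <- map$ref_key[match(mp$res_i, map$mod_key)]
  mp_j <- map$ref_key[match(mp$res_j, map$mod_key)]
  mapped <- !is.na(mp_i) & !is.na(mp_j)

  strict_tag <- function(df, ki, kj) {
    # orient edge/orientation annotation consistently with sorted keys
    swap <- ki > kj
    e1 <- ifelse(swap, df$edge_j, df$edge_i)
    e2 <- ifelse(swap, df$edge_i, df$edge_j)
    paste(e1, e2, df$orientation)
  }
  ref_ids <- if (strict && nrow(rp) > 0) {
    pair_id(rp$res_i, rp$res_j, strict_tag(rp, rp$res_i, rp$res_j))
  } else if (nrow(rp) > 0) pair_id(rp$res_i, rp$res_j) else character(0)
  mod_ids <- if (strict && nrow(mp) > 0) {
    pair_id(mp_i, mp_j, strict_tag(mp, mp_i, mp_j))
  } else if (nrow(mp) > 0) pair_id(mp_i, mp_j) else character(0)

  ref_cat <- ifelse(rp$canonical_wc, "wc", "nwc")
  mod_match <- mapped & mod_ids %in% ref_ids
  ref_match <- ref_ids %in% mod_ids[mapped]
  # FP category from the model's own annotation
  mod_cat <- ifelse(mp$canonical_wc, "wc", "nwc")

  counts <- function(cat) {
    tp <- sum(ref_match & ref_cat == cat)
    fn <- sum(!ref_match & ref_cat == cat)
    fp <- sum(!mod_match & mod_cat == cat)
    c(tp = tp, fp = fp, fn = fn)
  }
  wc <- counts("wc"); nwc <- counts("nwc")

  rs <- reference_set$stacks
  ms <- model_set$stacks
  ms_i <- map$ref_key[match(ms$res_i, map$mod_key)]
  ms_j <- map$ref_key[match(ms$res_j, map$mod_key)]
  s_mapped <- !is.na(ms_i) & !is.na(ms_j)
  ref_sid <- if (nrow(rs) > 0) pair_id(rs$res_i, rs$res_j) else character(0)
  mod_sid <- if (nrow(ms) > 0) pair_id(ms_i, ms_j) else character(0)
  s_tp <- sum(ref_sid %in% mod_sid[s_mapped])
  s_fn <- length(ref_sid) - s_tp
  s_fp <- sum(!(s_mapped & mod_sid %in% ref_sid))

  tibble(
    category = c("wc", "nwc", "stack", "all"),
    tp = unname(c(wc["tp"], nwc["tp"], s_tp, wc["tp"] + nwc["tp"] + s_tp)),
    fp = unname(c(wc["fp"], nwc["fp"], s_fp, wc["fp"] + nwc["fp"] + s_fp)),
    fn = unname(c(wc["fn"], nwc["fn"], s_fn, wc["fn"] + nwc["fn"] + s_fn))
  )
}

#' Interaction Network Fidelity
#'
#' `INF = sqrt(PPV x STY)` with `PPV = TP/(TP+FP)` (precision) and
#' `STY = TP/(TP+FN)` (sensitivity).  With an empty reference category
#' (`TP + FN = 0`) the score is undefined and reported as `NA`, never 0;
#' `TP = 0` against a nonempty reference gives 0.
#'
#' @param tp,fp,fn Non-negative counts (vectorised).
#' @return INF values in [0, 1] or `NA`.
#' @examples
#' inf_score(4, 0, 0)  # 1
#' inf_score(2, 1, 2)  # sqrt((2/3) * (1/2)) = 0.5774
#' @export
inf_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0, na.rm = TRUE)) abort("negative counts")
  out <- rep(NA_real_, length(tp))
  nonempty <- (tp + fn) > 0
  zero <- nonempty & tp == 0
  pos <- nonempty & tp > 0
  out[zero] <- 0
  out[pos] <- sqrt((tp[pos] / (tp[pos] + fp[pos])) *
                     (tp[pos] / (tp[pos] + fn[pos])))
  out
}

#' Deformation Index
#'
#' `DI = RMSD / INF`: the superposition RMSD inflated by the failure to
#' reproduce the reference interaction network.  Undefined (NA) when INF is
#' 0 or undefined.
#'
#' @param rmsd RMSD in Angstrom (>= 0).
#' @param inf_value INF in (0, 1], or 0/NA.
#' @return DI in Angstrom, or `NA`.
#' @export
deformation_index <- function(rmsd, inf_value) {
  out <- rmsd / inf_value
  out[is.na(inf_value) | inf_value == 0] <- NA_real_
  out
}

#' INF breakdown of a model against a reference
#'
#' Convenience wrapper: annotates both structures, matches the interaction
#' networks and returns counts plus INF per category.
#'
#' @inheritParams match_interactions
#' @param reference,model `rna_structure` objects.
#' @return Tibble: `category`, `tp`, `fp`, `fn`, `inf`.
#' @export
inf_breakdown <- function(reference, model, correspondence, strict = FALSE) {
  counts <- match_interactions(interactions_of(reference),
                               interactions_of(model),
                               correspondence, strict = strict)
  counts$inf <- inf_score(counts$tp, counts$fp, counts$fn)
  counts
}

#' Deformation Profile matrix
#'
#' For each paired residue i, the model is superposed onto the reference
#' using only residue i's paired atoms; entry (i, j) is then the mean
#' Euclidean distance over residue j's paired atoms under that anchored
#' motion.  Rows expose how well the neighbourhood of each anchor predicts
#' the rest of the structure, separating local from global deformation.
#'
#' @inheritParams paired_atoms
#' @param anchor_selection Atom selection used both for anchoring and
#'   measuring (default all heavy atoms).
#' @param domains Optional domain table (`name`, `chain`, `start`, `end`;
#'   1-based inclusive residue numbers) for block summaries.
#' @return An `rna_dp`: list with `values` (N x N matrix, Angstrom, anchor
#'   rows x measured columns, reference keys as dimnames),
#'   `domain_summaries` (tibble `domain`, `min`, `mean`, `max`) and
#'   `skipped` (anchors with fewer than 3 usable atoms).
#' @export
deformation_profile <- function(reference, model, correspondence = NULL,
                                anchor_selection = "all-heavy",
                                domains = NULL) {
  if (is.null(correspondence)) {
    correspondence <- build_correspondence(reference, model)
  }
  pa <- paired_atoms(reference, model, correspondence, anchor_selection)
  keys <- unique(pa$meta$ref_key)
  n <- length(keys)
  grp <- match(pa$meta$ref_key, keys)
  values <- matrix(NA_real_, n, n, dimnames = list(keys, keys))
  skipped <- character(0)
  for (i in seq_len(n)) {
    sel <- grp == i
    if (sum(sel) < 3) {
      skipped <- c(skipped, keys[i])
      next
    }
    sp <- tryCatch(kabsch_superpose(pa$P[sel, , drop = FALSE],
                                    pa$Q[sel, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(sp)) {
      skipped <- c(skipped, keys[i])
      next
    }
    fitted <- sweep(pa$Q %*% t(sp$rotation), 2, sp$translation, "+")
    d <- sqrt(rowSums((pa$P - fitted)^2))
    values[i, ] <- vapply(seq_len(n), function(j) mean(d[grp == j]),
                          numeric(1))
  }
  values[, colnames(values) %in% skipped] <- NA_real_

  summaries <- dp_domain_summaries(values, keys, domains)
  structure(
    list(values = values, domain_summaries = summaries,
         anchor_selection = anchor_selection, skipped = skipped),
    class = "rna_dp"
  )
}

dp_domain_summaries <- function(values, keys, domains) {
  block_summary <- function(name, members) {
    block <- values[members, members, drop = FALSE]
    tibble(domain = name,
           min = suppressWarnings(min(block, na.rm = TRUE)),
           mean = mean(block, na.rm = TRUE),
           max = suppressWarnings(max(block, na.rm = TRUE)))
  }
  out <- list(block_summary("(all)", rep(TRUE, length(keys))))
  if (!is.null(domains)) {
    domains <- as_tibble(domains)
    needed <- c("name", "chain", "start", "end")
    if (!all(needed %in% names(domains))) {
      abort("domains must have columns name, chain, start, end")
    }
    parsed <- parse_keys(keys)
    overlap_seen <- rep(0L, length(keys))
    for (r in seq_len(nrow(domains))) {
      members <- parsed$chain == domains$chain[r] &
        parsed$resno >= domains$start[r] & parsed$resno <= domains$end[r]
      overlap_seen <- overlap_seen + as.integer(members)
      if (!any(members)) next
      out[[length(out) + 1]] <- block_summary(domains$name[r], members)
    }
    if (any(overlap_seen > 1)) {
      warn("overlapping domain definitions; residues reported in each")
    }
  }
  bind_rows(out)
}

# parse "chain:number[^icode]" keys back into parts
parse_keys <- function(keys) {
  chain <- sub(":.*$", "", keys)
  rest <- sub("^[^:]*:", "", keys)
  icode <- ifelse(grepl("\\^", rest), sub("^.*\\^", "", rest), "")
  resno <- as.integer(sub("\\^.*$", "", rest))
  list(chain = chain, resno = resno, icode = icode)
}

#' @export
print.rna_dp <- function(x, ...) {
  v <- x$values
  cat(sprintf("<rna_dp> %d x %d (anchor x measured), mean = %.3f A, max = %.3f A\n",
              nrow(v), ncol(v), mean(v, na.rm = TRUE),
              if (all(is.na(v))) NA else max(v, na.rm = TRUE)))
  invisible(x)
}

#' @method tidy rna_dp
#' @export
tidy.rna_dp <- function(x, ...) {
  v <- x$values
  tibble(
    anchor = rep(rownames(v), times = ncol(v)),
    measured = rep(colnames(v), each = nrow(v)),
    value = as.vector(v)
  )
}

#' @method glance rna_dp
#' @export
glance.rna_dp <- function(x, ...) {
  v <- x$values
  tibble(n = nrow(v), mean = mean(v, na.rm = TRUE),
         min = suppressWarnings(min(v, na.rm = TRUE)),
         max = suppressWarnings(max(v, na.rm = TRUE)),
         n_skipped_anchors = length(x$skipped))
}
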