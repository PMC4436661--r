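#' Assess predicted models against a reference structure
#'
#' Runs the full assessment pipeline for each model: residue
#' correspondence, all-heavy superposition RMSD, interaction-network
#' annotation and INF by category (canonical Watson-Crick, non-Watson-Crick,
#' stacking), Deformation Index, torsion-space MCQ, and the Clash Score.
#' Models that fail to parse or score are recorded as failed rows and the
#' run continues.
#'
#' @param reference Path to the reference PDB file, or an `rna_structure`.
#' @param models Character vector of model paths, or a (optionally named)
#'   list of `rna_structure` objects.
#' @param mode Correspondence mode (see [build_correspondence()]).
#' @param selection Atom selection for RMSD (see [paired_atoms()]).
#' @param chain_map Optional chain mapping (reference -> model ids).
#' @param strict Strict interaction matching (edge + orientation identity).
#' @param rank_by Ranking key, `"rmsd"` (default, ascending; ties broken by
#'   DI, then label), or any numeric report column.
#' @return An `rna_report` tibble, one row per model, ranked.  Undefined
#'   INF categories (empty reference category) are `NA`, never 0.
#' @examples
#' ref <- build_helix("GGCGCAAUCC")
#' mod <- perturb(ref, perturb_noise(0.5, seed = 1))
#' assess(ref, list(decoy = mod))
#' @export
assess <- function(reference, models, mode = "by-alignment",
                   selection = "all-heavy", chain_map = NULL,
                   strict = FALSE, rank_by = "rmsd") {
  ref <- if (inherits(reference, "rna_structure")) reference else
    read_pdb(reference)
  if (inherits(models, "rna_structure")) models <- list(models)
  if (is.character(models)) models <- as.list(models)

  ref_ints <- interactions_of(ref)
  ref_tors <- compute_torsions(ref)

  score_one <- function(m, label) {
    mod <- if (inherits(m, "rna_structure")) m else read_pdb(m)
    if (!is.null(label) && nzchar(label)) mod$label <- label
    corr <- build_correspondence(ref, mod, mode = mode,
                                 chain_map = chain_map)
    sp <- rmsd_between(ref, mod, corr, selection = selection)
    counts <- match_interactions(ref_ints, interactions_of(mod), corr,
                                 strict = strict)
    counts$inf <- inf_score(counts$tp, counts$fp, counts$fn)
    infs <- setNames(counts$inf, counts$category)
    mcq_res <- mcq_global(ref_tors, compute_torsions(mod), corr)
    cs <- clash_score(mod)
    tibble(
      model = mod$label,
      rmsd = sp$rmsd,
      inf_all = infs[["all"]], inf_wc = infs[["wc"]],
      inf_nwc = infs[["nwc"]], inf_stack = infs[["stack"]],
      di = deformation_index(sp$rmsd, infs[["all"]]),
      di_wc = deformation_index(sp$rmsd, infs[["wc"]]),
      di_nwc = deformation_index(sp$rmsd, infs[["nwc"]]),
      di_stack = deformation_index(sp$rmsd, infs[["stack"]]),
      mcq = mcq_res$global_value,
      clash = as.numeric(cs),
      atom_pairs_used = sp$atom_pairs_used,
      unmatched_reference = length(corr$unmatched_reference),
      unmatched_model = length(corr$unmatched_model),
      angles_compared = mcq_res$angles_compared,
      has_hydrogens = has_hydrogens(mod),
      failed = FALSE, error = NA_character_
    )
  }

  labels <- names(models) %||% rep("", length(models))
  rows <- lapply(seq_along(models), function(i) {
    tryCatch(
      score_one(models[[i]], labels[i]),
      error = function(e) {
        lab <- if (nzchar(labels[i])) labels[i] else
          if (is.character(models[[i]])) basename(models[[i]]) else
            paste0("model_", i)
        tibble(model = lab, rmsd = NA_real_, inf_all = NA_real_,
               inf_wc = NA_real_, inf_nwc = NA_real_, inf_stack = NA_real_,
               di = NA_real_, di_wc = NA_real_, di_nwc = NA_real_,
               di_stack = NA_real_, mcq = NA_real_, clash = NA_real_,
               atom_pairs_used = NA_integer_,
               unmatched_reference = NA_integer_,
               unmatched_model = NA_integer_, angles_compared = NA_integer_,
               has_hydrogens = NA, failed = TRUE,
               error = conditionMessage(e))
      })
  })
  report <- bind_rows(rows)

  key <- report[[rank_by]]
  ord <- order(ifelse(report$failed, Inf, key),
               ifelse(report$failed, Inf, report$di), report$model)
  report$rank <- NA_integer_
  scored <- !report$failed
  report$rank[ord[seq_len(sum(scored))]] <- seq_len(sum(scored))
  report <- report[ord, ]
  class(report) <- c("rna_report", class(report))
  attr(report, "reference_label") <- ref$label
  attr(report, "rank_by") <- rank_by
  report
}

#' Write an assessment report to CSV and/or JSON
#'
#' Numeric values are written at 4 decimal places in both formats;
#' undefined values are `NA` (CSV) / `null` (JSON).  Output is byte-stable
#' for identical inputs (no timestamps).
#'
#' @param report An `rna_report`.
#' @param csv,json Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  out <- as_tibble(report)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) round(v, 4))
  if (!is.null(csv)) {
    write.csv(out, csv, row.names = FALSE, quote = FALSE, na = "NA")
  }
  if (!is.null(json)) {
    jsonlite::write_json(out, json, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' @export
print.rna_report <- function(x, ...) {
  cat(sprintf("<rna_report> %d model(s) vs '%s', ranked by %s\n",
              nrow(x), attr(x, "reference_label"), attr(x, "rank_by")))
  cols <- c("rank", "model", "rmsd", "di", "inf_all", "inf_wc", "inf_nwc",
            "inf_stack", "mcq", "clash")
  print(as_tibble(x)[, intersect(cols, names(x))])
  invisible(x)
}

#' @method tidy rna_report
#' @export
tidy.rna_report <- function(x, ...) {
  as_tibble(x) %>%
    select("model", "rank", "rmsd", "di", "inf_all", "inf_wc", "inf_nwc",
           "inf_stack", "mcq", "clash") %>%
    tidyr::pivot_longer(cols = -c("model", "rank"), names_to = "metric",
                        values_to = "value")
}

#' @method glance rna_report
#' @export
glance.rna_report <- function(x, ...) {
  ok <- !x$failed
  tibble(
    n_models = nrow(x), n_failed = sum(x$failed),
    mean_rmsd = mean(x$rmsd[ok]), best_rmsd = suppressWarnings(min(x$rmsd[ok])),
    best_model = if (any(ok)) x$model[which.min(ifelse(ok, x$rmsd, Inf))]
      else NA_character_
  )
}

#' Export a Deformation Profile matrix (and domain summary) as CSV
#'
#' @inheritParams deformation_profile
#' @param out Path of the matrix CSV (rows = anchor residues, columns =
#'   measured residues, 4 decimal places).
#' @param domain_out Optional path for the per-domain min/mean/max summary.
#' @param heatmap Optional path for an SVG heatmap of the matrix.
#' @return Invisibly, the `rna_dp` object.
#' @export
dp_export <- function(reference, model, correspondence = NULL,
                      anchor_selection = "all-heavy", domains = NULL,
                      out, domain_out = NULL, heatmap = NULL) {
  dp <- deformation_profile(reference, model, correspondence,
                            anchor_selection, domains)
  m <- round(dp$values, 4)
  df <- data.frame(anchor = rownames(m), m, check.names = FALSE)
  write.csv(df, out, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(domain_out)) {
    ds <- dp$domain_summaries
    ds[c("min", "mean", "max")] <- lapply(ds[c("min", "mean", "max")],
                                          round, 4)
    write.csv(ds, domain_out, row.names = FALSE, quote = FALSE, na = "NA")
  }
  if (!is.null(heatmap)) {
    if (capabilities("cairo")) {
      grDevices::svg(heatmap, width = 7, height = 6)
      print(autoplot(dp))
      grDevices::dev.off()
    } else {
      warn("SVG device unavailable; heatmap not written")
    }
  }
  invisible(dp)
}

#' Read a domain definition file
#'
#' CSV with columns `name`, `chain`, `start`, `end` (1-based inclusive
#' residue numbers).
#'
#' @param path CSV path.
#' @return Tibble of domain definitions.
#' @export
read_domains <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
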