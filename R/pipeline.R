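#' Full reconstruction pipeline: contacts to selected 3D model
#'
#' Reads a contact list, bins it to a binary bead-pair matrix, imputes
#' contact confidences with the 2D Gaussian kernel, anneals `n_models`
#' replicate structures (replicate m seeded with `seed + m - 1`), selects
#' the consensus model by average TM-score, optionally refines it to a
#' higher resolution, and evaluates the result. When `out_dir` is given,
#' writes the selected structure (CSV + PDB), the per-replicate loss traces
#' and ensemble similarity matrix (TSV), and a JSON run report carrying the
#' fully resolved configuration and all seeds.
#'
#' @param contacts Path to a contact-list file, or a `contact_matrix`.
#' @param chrom Chromosome name (required when `contacts` is a path).
#' @param chrom_length Chromosome length in bp (required for a path).
#' @param resolution Bead size in bp (default 500000).
#' @param impute_params An [impute_params()] object.
#' @param energy_params An [energy_params()] object.
#' @param config An [anneal_config()] (seed, replicate count, schedule).
#' @param refine_ratio If non-`NULL`, refine the selected model to
#'   `resolution / refine_ratio` (e.g. 10: 500 kb to 50 kb). The fine theta
#'   matrix is recomputed from the contacts re-binned at the fine resolution.
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `selected`, `models`, `ensemble`, `theta`,
#'   `evaluation`, `refined` (or `NULL`) and `report`.
#' @export
run_pipeline <- function(contacts, chrom = NULL, chrom_length = NULL,
                         resolution = 500000,
                         impute_params = scLJfold::impute_params(),
                         energy_params = scLJfold::energy_params(),
                         config = anneal_config(),
                         refine_ratio = NULL, out_dir = NULL) {
  records <- NULL
  if (inherits(contacts, "contact_matrix")) {
    cm <- contacts
    resolution <- cm$resolution
  } else {
    stopifnot(!is.null(chrom), !is.null(chrom_length))
    records <- read_contacts(contacts, chrom)
    cm <- bin_to_matrix(records, resolution, chrom_length, chrom = chrom)
  }
  theta <- gaussian_impute(cm, impute_params)

  seeds <- config$seed + seq_len(config$n_models) - 1L
  models <- vector("list", config$n_models)
  traces <- vector("list", config$n_models)
  for (m in seq_len(config$n_models)) {
    cfg_m <- config
    cfg_m$seed <- seeds[m]
    fit <- anneal(theta, energy_params, cfg_m, resolution = resolution)
    models[[m]] <- fit$conformation
    traces[[m]] <- fit$trace
  }
  if (config$n_models > 1L) {
    sel <- select_best(models)
  } else {
    warning("single replicate requested; model selection skipped")
    sel <- list(index = 1L, ensemble = NULL)
  }
  best <- models[[sel$index]]
  evaluation <- evaluate_structure(theta, best, resolution = resolution)

  refined <- NULL
  if (!is.null(refine_ratio)) {
    if (is.null(records)) {
      stop("refinement requires a contact-list path (fine-scale re-binning)")
    }
    fine_res <- resolution / refine_ratio
    l_fine <- refine_ratio * (cm$n_beads - 1L) + 1L
    # the fine chain spans ratio*(l-1)+1 beads, i.e. it ends at the start of
    # the last coarse bead; contacts falling beyond that span are clamped
    # into the terminal fine bead
    span <- l_fine * fine_res
    rec_f <- records
    rec_f$pos_a <- pmin(rec_f$pos_a, span)
    rec_f$pos_b <- pmin(rec_f$pos_b, span)
    cm_fine <- bin_to_matrix(rec_f, fine_res, chrom_length = span,
                             chrom = chrom)
    theta_fine <- gaussian_impute(cm_fine, impute_params)
    cfg_r <- config
    cfg_r$seed <- config$seed + config$n_models
    refined <- refine_high_resolution(best, theta_fine, energy_params,
                                      cfg_r, ratio = refine_ratio)
  }

  report <- list(
    tool = "scLJfold",
    version = as.character(utils::packageVersion("scLJfold")),
    chrom = cm$chrom, resolution = resolution, n_beads = cm$n_beads,
    n_contacts = sum(cm$values[upper.tri(cm$values)]),
    impute_params = unclass(impute_params),
    energy_params = unclass(energy_params),
    anneal_config = unclass(config),
    master_seed = config$seed, model_seeds = seeds,
    selected_model = sel$index,
    final_loss = total_loss(best, theta, energy_params),
    evaluation = list(
      pearson_r = evaluation$pearson$r, pearson_p = evaluation$pearson$p,
      n_pairs = evaluation$pearson$n_pairs,
      pofs_slope = evaluation$pofs$slope,
      rg_raw = evaluation$rg$rg_raw,
      rg_normalized = evaluation$rg$rg_normalized))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_structure(best, file.path(out_dir, "selected_structure.csv"), "csv")
    write_structure(best, file.path(out_dir, "selected_structure.pdb"), "pdb")
    trace_all <- do.call(rbind, lapply(seq_along(traces), function(m) {
      cbind(model = m, traces[[m]])
    }))
    utils::write.table(trace_all, file.path(out_dir, "loss_traces.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(sel$ensemble)) {
      utils::write.table(sel$ensemble$scores,
                         file.path(out_dir, "ensemble_tm_scores.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(refined)) {
      write_structure(refined$conformation,
                      file.path(out_dir, "refined_structure.csv"), "csv")
    }
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(selected = best, models = models, ensemble = sel$ensemble,
                 theta = theta, evaluation = evaluation, refined = refined,
                 report = report, traces = traces))
}
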