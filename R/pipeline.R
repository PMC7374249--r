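#' Run the end-to-end signature-development pipeline
#'
#' Orchestrates the stages on one cohort: generate (or accept) data,
#' calibrate the five published signatures in drug-adjusted and unadjusted
#' variants, run the two-stage consensus development, evaluate everything
#' (cross-validated and apparent T1 performance, drug influence, T1/T2
#' agreement), and write all artifacts plus a manifest to `out_dir`. All
#' randomness flows from the single `seed`, so a rerun with the same inputs
#' is byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional list with `expr` and `samples`; default: a
#'   synthetic cohort from [generate_cohort()] under `config$cohort`.
#' @param config List of stage parameters: `cohort` (a
#'   [synthetic_config()]), `signatures` (names from [tol_signatures()],
#'   default the five published sets), `variants` (`"both"`, `"original"`),
#'   `repeats`, `folds`, `inner_repeats`, `consensus` (logical),
#'   `threshold`, `alpha_select`, `alpha_final`.
#' @param seed Master seed.
#' @return Invisibly, a list with the comparison `report` (one row per
#'   signature variant, shaped like the published comparison table), the
#'   fitted objects, and the manifest path.
#' @export
run_pipeline <- function(out_dir, cohort = NULL, config = list(), seed = 1) {
  defaults <- list(cohort = synthetic_config(),
                   signatures = c("GAMBIT-g9", "GAMSTER-g4", "ROEDDER-g3",
                                  "NEWELL-g2", "DANGER-g6"),
                   variants = "both", repeats = 100, folds = 6,
                   inner_repeats = 10, consensus = TRUE, threshold = 0.75,
                   alpha_select = 0.95, alpha_final = 0.05)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort))
    cohort <- generate_cohort(config$cohort, seed = seed)
  expr <- cohort$expr
  samples <- cohort$samples
  write_expression(expr, file.path(out_dir, "expression.csv"))
  write_clinical(samples, file.path(out_dir, "clinical.csv"))

  sigs <- tol_signatures()[config$signatures]
  fits <- list()
  rows <- list()
  t2 <- samples$timepoint == "T2"
  sig_seed <- seed
  for (sig in sigs) {
    variants <- if (identical(config$variants, "both")) c(FALSE, TRUE)
                else sig$drug_adjusted
    for (adj in variants) {
      sig_seed <- sig_seed + 1L
      fit <- tolsig(expr, samples, sig, drug_adjusted = adj,
                    folds = config$folds, repeats = config$repeats,
                    inner_repeats = config$inner_repeats, seed = sig_seed)
      key <- sprintf("%s_%s", sig$name, if (adj) "adjusted" else "unadjusted")
      fits[[key]] <- fit
      rows[[key]] <- pipeline_report_row(fit, expr, samples)
      write_model_bundle(fit$bundle, file.path(out_dir, paste0(key, "_bundle.json")))
      utils::write.csv(
        data.frame(sample_id = rownames(fit$cv$probabilities),
                   fit$cv$probabilities, check.names = FALSE),
        file.path(out_dir, paste0(key, "_cv_probabilities.csv")),
        row.names = FALSE)
    }
  }
  consensus <- NULL
  if (isTRUE(config$consensus)) {
    consensus <- build_combined_pipeline(
      expr, samples, threshold = config$threshold,
      alpha_select = config$alpha_select, alpha_final = config$alpha_final,
      folds = config$folds, repeats = config$repeats,
      inner_repeats = config$inner_repeats, seed = sig_seed + 1L)
    rows[["COMBINED-all"]] <- pipeline_report_row(consensus$fit_all, expr, samples)
    if (!is.null(consensus$fit_consensus)) {
      rows[["COMBINED-consensus"]] <-
        pipeline_report_row(consensus$fit_consensus, expr, samples)
      write_model_bundle(consensus$fit_consensus$bundle,
                         file.path(out_dir, "COMBINED_consensus_bundle.json"))
    }
    utils::write.csv(
      data.frame(gene = names(consensus$report$frequency),
                 retention = consensus$report$frequency,
                 selected = names(consensus$report$frequency) %in%
                   consensus$report$selected),
      file.path(out_dir, "consensus_retention.csv"), row.names = FALSE)
  }
  report <- do.call(rbind, rows)
  utils::write.csv(report, file.path(out_dir, "comparison.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tolsig")),
    seed = seed,
    config = config[setdiff(names(config), "cohort")],
    n_samples = nrow(samples), n_t2 = sum(t2),
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                             pattern = "\\.(csv|json)$"))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, fits = fits, consensus = consensus,
                 manifest = manifest_path))
}

# One comparison-table row: cross-validated and apparent T1 performance,
# plus T2 agreement when follow-up samples exist.
pipeline_report_row <- function(fit, expr, samples) {
  sm <- summary(fit)
  t2 <- samples$timepoint == "T2" & samples$group %in% c("TOL", "ST", "CR")
  kappa_t2 <- NA_real_
  auc_t2 <- NA_real_
  if (any(t2)) {
    s2 <- samples[t2, , drop = FALSE]
    p2 <- predict_cohort(fit$bundle, expr[s2$sample_id, , drop = FALSE], s2)
    auc_t2 <- auc_delong(p2, s2$group == "TOL")[["auc"]]
    # match T1 and T2 samples of the same patients
    s1 <- samples[samples$timepoint == "T1" &
                    samples$patient_id %in% s2$patient_id, , drop = FALSE]
    p1 <- fit$probabilities[s1$sample_id]
    ord <- match(s2$patient_id, s1$patient_id)
    kappa_t2 <- cohens_kappa(p1[ord] > fit$bundle$cutoff,
                             p2 > fit$bundle$cutoff)$kappa
  }
  data.frame(
    signature = fit$signature$name,
    drug_adjusted = fit$drug_adjusted,
    cv_auc_median = sm$cv_auc[["median"]],
    cv_auc_p2.5 = sm$cv_auc[["p2.5"]], cv_auc_p97.5 = sm$cv_auc[["p97.5"]],
    cv_spec_median = sm$cv_specificity[["median"]],
    t1_auc = sm$final_auc[["auc"]],
    t1_auc_ci_low = sm$final_auc[["ci_low"]],
    t1_auc_ci_high = sm$final_auc[["ci_high"]],
    cutoff = fit$bundle$cutoff,
    sensitivity = sm$classification$sensitivity,
    specificity = sm$classification$specificity,
    tol_pos_st = sm$classification$tol_pos_st,
    tol_pos_cr = sm$classification$tol_pos_cr,
    t2_auc = auc_t2, kappa_t1_t2 = kappa_t2,
    row.names = NULL)
}
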