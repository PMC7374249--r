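# Shared fixtures, built in code. Cohorts are memoized per (size, seed) so
# test files can reuse them without regenerating.

.cohort_cache <- new.env(parent = emptyenv())

# Reduced synthetic cohort: same structure as the reference cohort but
# desk-scale group sizes, for fast structural tests.
small_cohort <- function(seed = 101, n_tol = 12, n_st = 48, n_cr = 12,
                         n_hc = 6, n_t2 = c(tol = 8, st = 12, cr = 4), ...) {
  key <- paste(seed, n_tol, n_st, n_cr, n_hc, paste(n_t2, collapse = "-"),
               length(list(...)), sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    cfg <- synthetic_config(n_tol = n_tol, n_st = n_st, n_cr = n_cr,
                            n_hc = n_hc, n_t2 = n_t2, ...)
    .cohort_cache[[key]] <- generate_cohort(cfg, seed = seed)
  }
  .cohort_cache[[key]]
}

# Full-size cohort under the reference study conditions (238 KTRs + 12 HC).
full_cohort <- function(seed = 1) {
  key <- paste0("full_", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(synthetic_config(), seed = seed)
  .cohort_cache[[key]]
}

# Minimal hand-built clinical table (2 TOL off drugs, 4 treated, 1 HC).
tiny_samples <- function() {
  sample_table(data.frame(
    sample_id = paste0("S", 1:7),
    patient_id = paste0("P", 1:7),
    timepoint = "T1",
    group = c("TOL", "TOL", "ST", "ST", "CR", "CR", "HC"),
    pred = c("off", "off", "on", "off", "on", "off", "off"),
    cni = c("off", "off", "cyc", "tac", "tac", "off", "off"),
    ap = c("off", "off", "mmf", "aza", "off", "mmf", "off"),
    dose_pred = c(NA, NA, 5, NA, 10, NA, NA),
    dose_cyc = c(NA, NA, 150, NA, NA, NA, NA),
    dose_tac = c(NA, NA, NA, 4, 6, NA, NA),
    dose_aza = c(NA, NA, NA, 100, NA, NA, NA),
    dose_mmf = c(NA, NA, 1000, NA, NA, 500, NA),
    stringsAsFactors = FALSE))
}

# Quick tolsig fit on the small cohort, memoized (used by several files).
small_fit <- function(signature = "COMBINED-g7", repeats = 3, seed = 11,
                      drug_adjusted = NULL) {
  key <- paste("fit", signature, repeats, seed,
               deparse(drug_adjusted), sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    coh <- small_cohort()
    .cohort_cache[[key]] <- tolsig(coh$expr, coh$samples, signature,
                                   drug_adjusted = drug_adjusted,
                                   repeats = repeats, inner_repeats = 2,
                                   seed = seed)
  }
  .cohort_cache[[key]]
}
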