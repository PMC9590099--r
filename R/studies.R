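#' Per-patient network analysis
#'
#' Runs the electrode-to-region stage for one patient: (optionally)
#' preprocesses the recording, estimates the time-averaged Pearson network,
#' assigns electrodes to atlas regions, builds the region network and its
#' symmetric-coverage restriction, and identifies SOZ regions (regions
#' containing any SOZ electrode).
#'
#' Synthetic recordings are referenced, artifact-free and zero-mean by
#' construction, so `preprocess = FALSE` (the default) analyzes them
#' directly; real recordings should use `preprocess = TRUE` to apply
#' artifact masking, common average reference and filtering first.
#'
#' @param patient a `synthetic_patient` (or compatible list).
#' @param atlas an [atlas_lookup()] table.
#' @param preprocess apply [reject_artifacts()], [common_average_reference()]
#'   and [filter_signals()] before network estimation.
#' @param subsample_resamples if > 0, balance electrode counts across
#'   homotopic regions by [subsample_balance()] with this many resamples.
#' @param max_assign_dist maximum electrode-to-centroid assignment distance (mm).
#' @return list with `network`, `region_network`, `symmetric`, `labels`,
#'   `soz_regions`.
#' @export
analyze_patient <- function(patient, atlas, preprocess = FALSE,
                            subsample_resamples = 0, max_assign_dist = 20) {
  rec <- patient$recording
  if (preprocess) {
    rec <- reject_artifacts(rec)
    rec <- common_average_reference(rec)
    rec <- filter_signals(rec)
  }
  net <- pearson_network(rec)
  labels <- assign_regions(patient$electrode_table, atlas,
                           max_dist = max_assign_dist)
  soz_regions <- setdiff(unique(labels[patient$electrode_table$soz_flag]),
                         "excluded")
  if (subsample_resamples > 0) {
    sym <- subsample_balance(net, labels, atlas,
                             n_resamples = subsample_resamples,
                             spike_rates = as.numeric(patient$spike_rates))
    rn <- region_network(net, labels,
                         spike_rates = as.numeric(patient$spike_rates))
  } else {
    rn <- region_network(net, labels,
                         spike_rates = as.numeric(patient$spike_rates))
    sym <- symmetric_coverage(rn, atlas)
  }
  list(network = net, region_network = rn, symmetric = sym, labels = labels,
       soz_regions = soz_regions)
}

#' Analyze every patient of a cohort
#'
#' @param cohort an `ieeg_cohort`.
#' @param ... passed to [analyze_patient()].
#' @return list of per-patient analyses, aligned with `cohort$patients`.
#' @export
analyze_cohort <- function(cohort, ...) {
  lapply(cohort$patients, analyze_patient, atlas = cohort$atlas, ...)
}

#' Cohort laterality feature table
#'
#' @param cohort an `ieeg_cohort`.
#' @param analyses per-patient analyses from [analyze_cohort()].
#' @return data.frame of eligible patients' laterality features.
#' @export
cohort_laterality_features <- function(cohort, analyses) {
  rows <- lapply(seq_along(cohort$patients), function(i) {
    laterality_features(analyses[[i]], cohort$patients[[i]], cohort$atlas)
  })
  do.call(rbind, rows)
}

#' Replicated SOZ-contrast study
#'
#' Generates `n_replicates` independent cohorts from variations of `spec`
#' (seeds derived from `seed`), runs the requested homotopic contrast on
#' each, and records T+, the two-sided p-value and the effect direction.
#' Used to measure the contrast's detection rate under an injected
#' connectivity reduction, and its false-positive rate under the null.
#'
#' @param spec a [cohort_spec()]; its `seed` is overridden per replicate.
#' @param n_replicates number of independent cohorts.
#' @param kind contrast kind (see [cohort_contrast()]).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return data.frame with one row per replicate: `T_plus`, `p`, `n_pairs`,
#'   `soz_lower` (TRUE when the median paired difference is negative).
#' @export
replicate_contrast_study <- function(spec, n_replicates = 50,
                                     kind = "regional", seed = 1L) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    sp <- spec
    sp$seed <- as.integer(seed + r)
    cohort <- generate_cohort(sp)
    analyses <- analyze_cohort(cohort)
    ct <- cohort_contrast(analyses, cohort$patients, cohort$atlas, kind = kind)
    inc <- ct$pairs[ct$pairs$included, , drop = FALSE]
    data.frame(replicate = r,
               T_plus = if (is.null(ct$test)) NA_real_ else ct$test$T_plus,
               p = if (is.null(ct$test)) NA_real_ else ct$test$p,
               n_pairs = nrow(inc),
               soz_lower = stats::median(inc$soz - inc$contra) < 0)
  })
  do.call(rbind, rows)
}
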