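#' Default pipeline configuration
#'
#' Mirrors the analysis defaults throughout the package: 2-s correlation
#' windows averaged over 1-min segments, 100 subsampling resamples, 1000
#' train/test splits with 2/3 training fraction, 0.5 laterality threshold,
#' and 1000 patient bootstraps for the mixed-effects model. Override any
#' entry via the `config` argument of [run_pipeline()].
#'
#' @return named list of configuration defaults.
#' @export
default_pipeline_config <- function() {
  list(seed = 1L,
       out_dir = "sozspatial-output",
       cohort = list(n_patients = 40L, fs = 256, duration_s = 60,
                     soz_conn_reduction = 0.5, spike_rate_ratio = 2),
       preprocess = list(enabled = TRUE, amp_thresh = 1000, flat_thresh = 0.1),
       atlas = list(max_assign_dist = 20),
       contrasts = list(enabled = TRUE, subsample_resamples = 0),
       laterality = list(enabled = TRUE, threshold = 0.5,
                         model_ids = c("connectivity", "spikes", "both")),
       spatial_null = list(enabled = TRUE, n_splits = 200, train_frac = 2 / 3,
                           stratify_by_implant = FALSE,
                           mixed_effects = FALSE, n_boot = 200))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

write_table <- function(df, dir, name, header) {
  path <- file.path(dir, name)
  con <- file(path, "w")
  writeLines(paste0("# ", header), con)
  close(con)
  suppressWarnings(utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  path
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates cohort generation, preprocessing, network estimation, atlas
#' mapping, the three homotopic SOZ contrasts, leave-one-patient-out
#' laterality classification, and the spatial-null split evaluation, writing
#' every summary table (tab-separated, stamped with the seed and a config
#' hash) plus a run log to the output directory. Stages can be disabled
#' individually; a fixed seed makes the whole bundle reproducible.
#'
#' @param config named list overriding [default_pipeline_config()] entries,
#'   or the path to a YAML file of such overrides.
#' @return invisibly, a list with the computed objects (`cohort`,
#'   `contrasts`, `laterality`, `spatial_null`) and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  # hash the analysis-relevant config only: the output path must not change it
  hash_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "out_dir")], hash_file)
  cfg_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)
  stamp <- sprintf("seed=%d config_md5=%s sozspatial=%s", cfg$seed, cfg_hash,
                   as.character(utils::packageVersion("sozspatial")))
  log <- c(sprintf("[%s] pipeline start: %s", format(Sys.time()), stamp))

  spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  cohort <- generate_cohort(spec)
  log <- c(log, sprintf("generated cohort: %d patients", spec$n_patients))

  analyses <- analyze_cohort(cohort, preprocess = isTRUE(cfg$preprocess$enabled),
                             subsample_resamples = cfg$contrasts$subsample_resamples,
                             max_assign_dist = cfg$atlas$max_assign_dist)
  results <- list(cohort = cohort, out_dir = cfg$out_dir)

  if (isTRUE(cfg$contrasts$enabled)) {
    contrasts <- lapply(c("regional", "intrahemispheric", "intrinsic"),
                        function(k) cohort_contrast(analyses, cohort$patients,
                                                    cohort$atlas, kind = k))
    names(contrasts) <- vapply(contrasts, `[[`, "", "kind")
    for (k in names(contrasts)) {
      write_table(contrasts[[k]]$pairs, cfg$out_dir,
                  paste0("contrast_", k, ".tsv"), stamp)
      t <- contrasts[[k]]$test
      if (!is.null(t)) {
        log <- c(log, sprintf("%s contrast: T+=%.1f p=%.4f (n=%d)", k,
                              t$T_plus, t$p, t$n_used))
      }
    }
    results$contrasts <- contrasts
  }

  if (isTRUE(cfg$laterality$enabled)) {
    feats <- cohort_laterality_features(cohort, analyses)
    lat <- list()
    if (!is.null(feats) && nrow(feats) >= 3L &&
        length(unique(feats$label)) == 2L) {
      for (m in cfg$laterality$model_ids) {
        lat[[m]] <- loo_crossval(feats, m, threshold = cfg$laterality$threshold)
        cm <- as.data.frame(lat[[m]]$confusion)
        write_table(cm, cfg$out_dir, paste0("laterality_", m, "_confusion.tsv"),
                    stamp)
        log <- c(log, sprintf(
          "laterality %s: accuracy=%.3f ppv=%.3f npv=%.3f", m,
          lat[[m]]$accuracy, lat[[m]]$ppv, lat[[m]]$npv))
      }
      summary_df <- data.frame(
        model = names(lat),
        accuracy = vapply(lat, `[[`, 0, "accuracy"),
        ppv = vapply(lat, `[[`, 0, "ppv"),
        npv = vapply(lat, `[[`, 0, "npv"))
      write_table(summary_df, cfg$out_dir, "laterality_summary.tsv", stamp)
    } else {
      log <- c(log, "laterality: skipped (too few eligible patients)")
    }
    results$laterality <- lat
  }

  if (isTRUE(cfg$spatial_null$enabled)) {
    feats <- cohort_electrode_features(cohort, analyses)
    ev <- evaluate_splits(feats, n_splits = cfg$spatial_null$n_splits,
                          train_frac = cfg$spatial_null$train_frac,
                          seed = cfg$seed)
    auc_df <- data.frame(model = ev$model_ids, mean_auc = ev$mean_auc,
                         ci_lo = ev$ci[1, ], ci_hi = ev$ci[2, ])
    write_table(auc_df, cfg$out_dir, "spatial_null_auc.tsv", stamp)
    write_table(as.data.frame(ev$p_values), cfg$out_dir,
                "spatial_null_pvalues.tsv", stamp)
    log <- c(log, sprintf("spatial null: mean AUC %s",
                          paste(sprintf("%s=%.3f", ev$model_ids, ev$mean_auc),
                                collapse = " ")))
    results$spatial_null <- ev
    if (isTRUE(cfg$spatial_null$stratify_by_implant)) {
      results$stratified <- stratified_evaluation(
        feats, n_splits = cfg$spatial_null$n_splits,
        train_frac = cfg$spatial_null$train_frac, seed = cfg$seed)
    }
    if (isTRUE(cfg$spatial_null$mixed_effects)) {
      me <- mixed_effects_association(feats, n_boot = cfg$spatial_null$n_boot,
                                      seed = cfg$seed)
      write_table(data.frame(odds_ratio = me$or, ci_lo = me$ci[1],
                             ci_hi = me$ci[2], p = me$p),
                  cfg$out_dir, "mixed_effects.tsv", stamp)
      log <- c(log, sprintf("mixed effects: OR=%.3f [%.3f, %.3f] p=%.4f",
                            me$or, me$ci[1], me$ci[2], me$p))
      results$mixed_effects <- me
    }
  }

  log <- c(log, sprintf("[%s] pipeline done", format(Sys.time())))
  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  invisible(results)
}
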