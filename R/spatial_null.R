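#' Kernel density of electrode sampling
#'
#' Truncated quadratic (Epanechnikov-type) kernel sum quantifying local
#' electrode sampling density:
#' density_i = (1 / radius^2) * sum_{j != i} (3 / pi) (1 - (d_ij / radius)^2)^2,
#' with zero contribution from electrodes beyond the search radius. By
#' default the radius is patient-specific: the distance between the two
#' electrodes furthest from each other, so every other electrode contributes
#' to every density. Raw densities are returned; z-normalize within patient
#' via [znormalize_within_patient()].
#'
#' @param coords numeric matrix/data.frame of 3-D electrode coordinates (mm).
#' @param radius search radius in mm; NULL uses the maximum pairwise distance.
#' @return numeric vector of raw densities, one per electrode.
#' @export
kernel_density <- function(coords, radius = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("kernel density undefined for < 2 electrodes")
  D <- as.matrix(stats::dist(coords))
  if (is.null(radius)) radius <- max(D)
  if (radius <= 0) stop("radius must be positive")
  K <- (3 / pi) * (1 - (D / radius)^2)^2
  K[D > radius] <- 0
  diag(K) <- 0
  unname(rowSums(K)) / radius^2
}

#' Electrode-level feature table for SOZ classification
#'
#' Assembles one row per included electrode across the cohort: coarse
#' anatomy, within-patient z-normalized kernel density, average Pearson
#' connectivity, and spike rate, plus the SOZ outcome flag, patient id and
#' implant type. Electrodes with excluded anatomy (outside the parcellation,
#' white matter) are dropped.
#'
#' @param cohort an `ieeg_cohort`.
#' @param analyses per-patient analyses from [analyze_cohort()].
#' @return data.frame of `ElectrodeFeatures` rows.
#' @export
cohort_electrode_features <- function(cohort, analyses) {
  rows <- lapply(seq_along(cohort$patients), function(i) {
    p <- cohort$patients[[i]]
    a <- analyses[[i]]
    et <- p$electrode_table
    anatomy <- cohort$atlas$coarse_anatomy[match(a$labels, cohort$atlas$region_id)]
    anatomy[a$labels == "excluded" | is.na(anatomy)] <- "excluded"
    keep <- anatomy != "excluded"
    if (sum(keep) < 3L) return(NULL)
    dens <- kernel_density(et[, c("x", "y", "z")])
    conn <- node_average_connectivity(a$network)
    zsafe <- function(v) tryCatch(znormalize_within_patient(v),
                                  error = function(e) rep(0, length(v)))
    data.frame(patient_id = p$patient_id,
               electrode = et$name[keep],
               coarse_anatomy = anatomy[keep],
               density_z = zsafe(dens[keep]),
               conn_z = zsafe(conn[keep]),
               spike_z = zsafe(as.numeric(p$spike_rates)[keep]),
               soz_flag = et$soz_flag[keep],
               implant_type = p$implant_type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$coarse_anatomy <- factor(out$coarse_anatomy,
                               levels = c("other cortex", "mesial temporal",
                                          "temporal neocortical"))
  out
}

soz_model_formulas <- list(
  "null" = soz_flag ~ coarse_anatomy + density_z,
  "null+conn" = soz_flag ~ coarse_anatomy + density_z + conn_z,
  "null+spikes" = soz_flag ~ coarse_anatomy + density_z + spike_z,
  "all" = soz_flag ~ coarse_anatomy + density_z + conn_z + spike_z)

#' Fit one SOZ-electrode logistic classifier
#'
#' Logistic regression with coarse anatomy as a categorical predictor
#' (reference: other cortex) plus the model-specific continuous predictors:
#' "null" adds density only (spatial sampling information, no EEG data),
#' "null+conn" adds average connectivity, "null+spikes" adds spike rate,
#' "all" adds both.
#'
#' @param train data.frame of electrode features with both outcome classes.
#' @param model_id one of "null", "null+conn", "null+spikes", "all".
#' @return fitted `glm` object; score held-out electrodes with
#'   `predict(fit, newdata, type = "response")`.
#' @export
fit_soz_classifier <- function(train, model_id = c("null", "null+conn",
                                                   "null+spikes", "all")) {
  model_id <- match.arg(model_id)
  if (length(unique(train$soz_flag)) < 2L) stop("single-class training data")
  suppressWarnings(stats::glm(soz_model_formulas[[model_id]],
                              family = stats::binomial(), data = train))
}

#' ROC curve by threshold sweep
#'
#' Stepwise ROC over unique score thresholds (descending), with ties handled
#' jointly so the trapezoidal area equals the rank (pairwise-comparison) AUC.
#'
#' @param scores numeric classifier scores (higher = more likely positive).
#' @param labels logical or 0/1 outcome.
#' @return list with `fpr`, `tpr` (including (0,0) and (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("ROC needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cut after each block of tied scores
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' AUC via the rank (Mann-Whitney) formulation
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted half -- identical to the trapezoidal area under the tie-aware
#' ROC curve.
#'
#' @inheritParams roc_curve
#' @return scalar AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# tpr at fixed fpr grid by stepwise interpolation of an ROC curve
roc_at_grid <- function(roc, grid) {
  stats::approx(roc$fpr, roc$tpr, xout = grid, method = "linear",
                ties = max, rule = 2)$y
}

#' Split-resampling evaluation of SOZ-electrode classifiers
#'
#' Repeatedly splits patients into training (`train_frac`) and testing sets;
#' all models share each split. Per split, each model is fit on the training
#' electrodes and its probabilities are scored on the pooled test electrodes
#' with an ROC/AUC. Splits with a single outcome class in either fold are
#' redrawn (and counted). ROC curves are averaged vertically on a fixed
#' false-positive-rate grid; AUC confidence intervals are 2.5/97.5
#' percentiles across splits; pairwise model comparisons use the counting
#' p-value of [auc_difference_pvalue()].
#'
#' @param features electrode feature table from [cohort_electrode_features()].
#' @param model_ids models to evaluate (see [fit_soz_classifier()]).
#' @param n_splits number of random splits.
#' @param train_frac fraction of patients used for training.
#' @param seed RNG seed.
#' @param fpr_grid false-positive-rate grid for ROC averaging.
#' @return a `split_evaluation`: per-split `auc` matrix, `mean_auc`, `ci`,
#'   averaged ROC curves, pairwise `p_values`, `n_redrawn`.
#' @export
evaluate_splits <- function(features,
                            model_ids = c("null", "null+conn", "null+spikes", "all"),
                            n_splits = 1000, train_frac = 2 / 3, seed = NULL,
                            fpr_grid = seq(0, 1, by = 0.02)) {
  if (!is.null(seed)) set.seed(seed)
  patients <- unique(features$patient_id)
  if (length(patients) < 3L) stop("need >= 3 patients")
  n_train <- max(1L, round(train_frac * length(patients)))
  if (n_train >= length(patients)) n_train <- length(patients) - 1L
  auc <- matrix(NA_real_, n_splits, length(model_ids),
                dimnames = list(NULL, model_ids))
  tpr_sum <- matrix(0, length(fpr_grid), length(model_ids),
                    dimnames = list(NULL, model_ids))
  n_redrawn <- 0L
  for (s in seq_len(n_splits)) {
    repeat {
      tr_pat <- sample(patients, n_train)
      train <- features[features$patient_id %in% tr_pat, , drop = FALSE]
      test <- features[!features$patient_id %in% tr_pat, , drop = FALSE]
      if (length(unique(train$soz_flag)) == 2L &&
          length(unique(test$soz_flag)) == 2L) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_splits) stop("cannot draw non-degenerate splits")
    }
    for (mi in seq_along(model_ids)) {
      fit <- fit_soz_classifier(train, model_ids[mi])
      prob <- suppressWarnings(stats::predict(fit, newdata = test, type = "response"))
      roc <- roc_curve(prob, test$soz_flag)
      auc[s, mi] <- roc$auc
      tpr_sum[, mi] <- tpr_sum[, mi] + roc_at_grid(roc, fpr_grid)
    }
  }
  mean_auc <- colMeans(auc)
  ci <- apply(auc, 2, stats::quantile, probs = c(0.025, 0.975))
  pm <- matrix(NA_real_, length(model_ids), length(model_ids),
               dimnames = list(model_ids, model_ids))
  for (i in seq_along(model_ids)) {
    for (j in seq_along(model_ids)) {
      if (i < j) {
        pm[i, j] <- pm[j, i] <-
          auc_difference_pvalue(auc[, i] - auc[, j])
      }
    }
  }
  structure(list(model_ids = model_ids, auc = auc, mean_auc = mean_auc,
                 ci = ci, mean_roc = list(fpr = fpr_grid,
                                          tpr = tpr_sum / n_splits),
                 p_values = pm, n_redrawn = n_redrawn,
                 n_splits = n_splits, train_frac = train_frac),
            class = "split_evaluation")
}

#' Two-tailed counting p-value for per-split AUC differences
#'
#' p = 2 * (min\[N(diff <= 0), N(diff >= 0)\] + 1) / (N_total + 1), clamped
#' to at most 1. Ties (diff = 0) count on both sides. The minimum attainable
#' value, when every difference lies strictly on one side, is
#' 2 / (N_total + 1).
#'
#' @param diffs numeric vector of per-split AUC differences.
#' @return scalar p-value in \[2/(N+1), 1\].
#' @export
auc_difference_pvalue <- function(diffs) {
  n <- length(diffs)
  if (n < 1L) stop("need at least one difference")
  min(1, 2 * (min(sum(diffs <= 0), sum(diffs >= 0)) + 1) / (n + 1))
}

#' Split evaluation stratified by implant type
#'
#' Runs [evaluate_splits()] independently within the stereo and
#' grid/strip/depth strata. Strata with fewer than 3 patients or a single
#' outcome class are skipped with a reason.
#'
#' @inheritParams evaluate_splits
#' @return named list of `split_evaluation` objects (or skip reasons) per
#'   implant type.
#' @export
stratified_evaluation <- function(features,
                                  model_ids = c("null", "null+conn",
                                                "null+spikes", "all"),
                                  n_splits = 1000, train_frac = 2 / 3,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (stratum in unique(features$implant_type)) {
    sub <- features[features$implant_type == stratum, , drop = FALSE]
    n_pat <- length(unique(sub$patient_id))
    if (n_pat < 3L || length(unique(sub$soz_flag)) < 2L) {
      out[[stratum]] <- paste("skipped:", n_pat, "patients")
      next
    }
    out[[stratum]] <- evaluate_splits(sub, model_ids, n_splits, train_frac)
  }
  out
}

#' Mixed-effects association between connectivity and SOZ membership
#'
#' Random-intercept logistic model over all electrodes (outcome: SOZ flag;
#' predictors: coarse anatomy, density_z, conn_z, spike_z; random intercept
#' per patient), reporting the odds ratio per normalized connectivity unit.
#' Uncertainty comes from a patient-level bootstrap: patients are resampled
#' with replacement `n_boot` times, the model refit, and the conn_z
#' coefficient collected; the CI is the 2.5/97.5 percentile of bootstrap
#' odds ratios and the two-sided p-value applies the sign-counting formula
#' to the bootstrap coefficients. Fits use `nAGQ = 0` (fast penalized
#' quasi-Laplace) so the bootstrap stays tractable; non-converging resamples
#' are excluded and counted.
#'
#' @param features electrode feature table from [cohort_electrode_features()].
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @return list with `or` (point estimate), `ci`, `p`, `coef` (fixed
#'   effects), `boot_or`, `n_failed`.
#' @export
mixed_effects_association <- function(features, n_boot = 1000, seed = NULL) {
  if (length(unique(features$patient_id)) < 5L) stop("need >= 5 patients")
  if (!is.null(seed)) set.seed(seed)
  form <- soz_flag ~ coarse_anatomy + density_z + conn_z + spike_z +
    (1 | patient_id)
  fit_one <- function(dat) {
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(form, data = dat, family = stats::binomial(), nAGQ = 0)))
    lme4::fixef(fit)
  }
  fe <- fit_one(features)
  patients <- unique(features$patient_id)
  by_pat <- split(features, features$patient_id)
  boot_coef <- rep(NA_real_, n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    draw <- sample(patients, length(patients), replace = TRUE)
    dat <- do.call(rbind, lapply(seq_along(draw), function(k) {
      d <- by_pat[[draw[k]]]
      d$patient_id <- paste0(d$patient_id[1], "_rep", k)  # copies stay distinct groups
      d
    }))
    cf <- tryCatch(fit_one(dat), error = function(e) NULL)
    if (is.null(cf) || !is.finite(cf[["conn_z"]])) {
      n_failed <- n_failed + 1L
    } else {
      boot_coef[b] <- cf[["conn_z"]]
    }
  }
  bc <- boot_coef[!is.na(boot_coef)]
  ci <- exp(stats::quantile(bc, c(0.025, 0.975)))
  p <- min(1, 2 * (min(sum(bc <= 0), sum(bc >= 0)) + 1) / (length(bc) + 1))
  list(or = exp(fe[["conn_z"]]), ci = ci, p = p, coef = fe,
       boot_or = exp(bc), n_failed = n_failed)
}
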