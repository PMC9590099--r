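#' Per-patient laterality features
#'
#' Computes, on the symmetric-coverage region network, the average left and
#' right intra-hemispheric connectivity, plus average left and right
#' hemispheric spike rates over electrodes within symmetric-coverage
#' regions. Eligible patients have a unilateral SOZ and at least two
#' symmetrically covered regions per hemisphere.
#'
#' @param analysis a per-patient analysis from [analyze_patient()].
#' @param patient the corresponding `synthetic_patient` (or compatible list
#'   with `patient_id`, `laterality`, `spike_rates`).
#' @param atlas an [atlas_lookup()] table.
#' @return one-row data.frame of features and label, or NULL when ineligible.
#' @export
laterality_features <- function(analysis, patient, atlas) {
  if (!patient$laterality %in% c("left", "right")) return(NULL)
  regnet <- analysis$symmetric
  retained <- regnet$retained
  hemi <- atlas$hemisphere[match(retained, atlas$region_id)]
  left_r <- retained[hemi == "left"]
  right_r <- retained[hemi == "right"]
  if (length(left_r) < 2L || length(right_r) < 2L) return(NULL)
  intra <- function(set) {
    sub <- regnet$adjacency[set, set, drop = FALSE]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }
  labels <- analysis$labels
  spike_side <- function(set) {
    idx <- which(labels %in% set)
    if (length(idx) == 0L) return(NA_real_)
    mean(patient$spike_rates[idx])
  }
  out <- data.frame(patient_id = patient$patient_id,
                    left_intra_conn = intra(left_r),
                    right_intra_conn = intra(right_r),
                    left_spikes = spike_side(left_r),
                    right_spikes = spike_side(right_r),
                    label = patient$laterality,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(as.numeric(out[1, 2:5])))) return(NULL)
  out
}

laterality_formulas <- list(
  connectivity = label_left ~ left_intra_conn + right_intra_conn,
  spikes = label_left ~ left_spikes + right_spikes,
  both = label_left ~ left_intra_conn + right_intra_conn + left_spikes + right_spikes)

#' Select laterality model predictors
#'
#' Model "connectivity" uses the two intra-hemispheric connectivity features,
#' "spikes" the two hemispheric spike-rate features, "both" all four.
#'
#' @param features data.frame from [laterality_features()] rows.
#' @param model_id one of "connectivity", "spikes", "both".
#' @return data.frame restricted to the model's predictors plus label columns.
#' @export
build_features <- function(features, model_id = c("connectivity", "spikes", "both")) {
  model_id <- match.arg(model_id)
  cols <- switch(model_id,
    connectivity = c("left_intra_conn", "right_intra_conn"),
    spikes = c("left_spikes", "right_spikes"),
    both = c("left_intra_conn", "right_intra_conn", "left_spikes", "right_spikes"))
  features[, c("patient_id", cols, "label"), drop = FALSE]
}

#' Leave-one-patient-out laterality classification
#'
#' For each patient, a plain maximum-likelihood logistic model (no
#' regularization) is fit on all other patients and predicts left-sided onset
#' when the fitted probability is >= `threshold`. Folds whose training data
#' contain a single class are skipped and counted. The confusion matrix is
#' summed over held-out patients; PPV/NPV are reported for detecting
#' left-sided onset.
#'
#' @param features data.frame of [laterality_features()] rows.
#' @param model_id one of "connectivity", "spikes", "both".
#' @param threshold probability cut for predicting left (>= predicts left).
#' @return list with `confusion` (true x predicted), `accuracy`, `ppv`,
#'   `npv`, `n_skipped`, `predictions`.
#' @export
loo_crossval <- function(features, model_id = c("connectivity", "spikes", "both"),
                         threshold = 0.5) {
  model_id <- match.arg(model_id)
  if (nrow(features) < 3L) stop("need >= 3 eligible patients")
  if (length(unique(features$label)) < 2L) stop("both classes must be present")
  dat <- build_features(features, model_id)
  dat$label_left <- as.integer(dat$label == "left")
  form <- laterality_formulas[[model_id]]
  pred <- rep(NA_character_, nrow(dat))
  n_skipped <- 0L
  for (i in seq_len(nrow(dat))) {
    train <- dat[-i, , drop = FALSE]
    if (length(unique(train$label_left)) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = train))
    prob <- suppressWarnings(stats::predict(fit, newdata = dat[i, , drop = FALSE],
                                            type = "response"))
    pred[i] <- if (prob >= threshold) "left" else "right"
  }
  ok <- !is.na(pred)
  confusion <- table(factor(dat$label[ok], levels = c("left", "right")),
                     factor(pred[ok], levels = c("left", "right")),
                     dnn = c("true", "predicted"))
  accuracy <- sum(diag(confusion)) / sum(confusion)
  ppv <- if (sum(confusion[, "left"]) > 0) {
    confusion["left", "left"] / sum(confusion[, "left"])
  } else NA_real_
  npv <- if (sum(confusion[, "right"]) > 0) {
    confusion["right", "right"] / sum(confusion[, "right"])
  } else NA_real_
  list(confusion = confusion, accuracy = accuracy, ppv = ppv, npv = npv,
       n_skipped = n_skipped,
       predictions = data.frame(patient_id = dat$patient_id, true = dat$label,
                                predicted = pred, stringsAsFactors = FALSE))
}
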