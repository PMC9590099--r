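# Homotopic SOZ contrasts on symmetric-coverage region networks.
# All three contrasts return list(soz = , contra = ) or NULL with an
# attr(, "reason") explaining the exclusion, so cohort-level tables can count
# exclusions the way the study design requires.

excluded_patient <- function(reason) {
  structure(list(), class = "excluded_patient", reason = reason)
}

is_excluded <- function(x) inherits(x, "excluded_patient") || is.null(x)

#' Reason a patient was excluded from a contrast
#'
#' @param x an excluded-patient marker returned by a contrast function.
#' @return character reason, or NULL for included patients.
#' @export
exclusion_reason <- function(x) attr(x, "reason")

#' Regional SOZ vs contralateral connectivity
#'
#' Compares the average connectivity incident to the SOZ regions against the
#' same computation on their homotopic (contralateral) regions, on a
#' symmetric-coverage region network. Edges internal to either comparison set
#' and edges between the two sets are excluded from both averages, keeping
#' the two quantities structurally parallel. SOZ regions whose homotopic
#' partner is itself an SOZ region (bilateral overlap) are dropped from the
#' contrast.
#'
#' @param regnet a [symmetric_coverage()] region network.
#' @param soz_regions character vector of SOZ region ids for the patient.
#' @param atlas an [atlas_lookup()] table.
#' @return list(soz, contra) of mean connectivities, or an excluded marker
#'   with a reason.
#' @export
soz_regional_connectivity <- function(regnet, soz_regions, atlas) {
  retained <- regnet$retained
  A_set <- intersect(soz_regions, retained)
  if (length(A_set) == 0L) return(excluded_patient("no SOZ region with symmetric coverage"))
  B_set <- homotopic_regions(atlas, A_set)
  overlap <- A_set[B_set %in% A_set]
  if (length(overlap) > 0L) {
    A_set <- setdiff(A_set, overlap)
    if (length(A_set) == 0L) {
      return(excluded_patient("all SOZ regions homotopically paired with SOZ regions"))
    }
    B_set <- homotopic_regions(atlas, A_set)
  }
  other <- setdiff(retained, union(A_set, B_set))
  if (length(other) == 0L) return(excluded_patient("no non-SOZ regions to connect to"))
  soz_vals <- regnet$adjacency[A_set, other, drop = FALSE]
  contra_vals <- regnet$adjacency[B_set, other, drop = FALSE]
  if (all(is.na(soz_vals)) || all(is.na(contra_vals))) {
    return(excluded_patient("no defined incident edges"))
  }
  list(soz = mean(soz_vals, na.rm = TRUE), contra = mean(contra_vals, na.rm = TRUE))
}

#' Intra-hemispheric connectivity, SOZ side vs contralateral
#'
#' Mean of defined within-hemisphere edges among retained regions, computed
#' separately for the SOZ side and the contralateral side. Requires a
#' unilateral SOZ and at least two symmetrically covered regions per
#' hemisphere (otherwise there are no within-hemisphere edges to average).
#'
#' @param regnet a [symmetric_coverage()] region network.
#' @param laterality "left" or "right".
#' @param atlas an [atlas_lookup()] table.
#' @return list(soz, contra) or an excluded marker.
#' @export
intrahemispheric_connectivity <- function(regnet, laterality, atlas) {
  if (!laterality %in% c("left", "right")) {
    return(excluded_patient("not unilateral"))
  }
  retained <- regnet$retained
  hemi <- atlas$hemisphere[match(retained, atlas$region_id)]
  ipsi <- retained[hemi == laterality]
  contra <- retained[hemi != laterality]
  if (length(ipsi) < 2L || length(contra) < 2L) {
    return(excluded_patient("fewer than two symmetric regions per hemisphere"))
  }
  hemi_mean <- function(set) {
    sub <- regnet$adjacency[set, set, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  s <- hemi_mean(ipsi)
  c_ <- hemi_mean(contra)
  if (is.na(s) || is.na(c_)) return(excluded_patient("no defined intra-hemispheric edges"))
  list(soz = s, contra = c_)
}

#' Intrinsic (within-SOZ) connectivity vs contralateral
#'
#' Mean of defined edges among the SOZ regions, against the same computation
#' among their homotopic regions. Requires the SOZ to span at least two
#' retained regions. SOZ regions homotopically paired with other SOZ regions
#' are dropped (the contralateral control would otherwise overlap the SOZ set).
#'
#' @inheritParams soz_regional_connectivity
#' @return list(soz, contra) or an excluded marker.
#' @export
intrinsic_soz_connectivity <- function(regnet, soz_regions, atlas) {
  retained <- regnet$retained
  A_set <- intersect(soz_regions, retained)
  B_set <- homotopic_regions(atlas, A_set)
  keep <- !(B_set %in% A_set)
  A_set <- A_set[keep]
  B_set <- B_set[keep]
  if (length(A_set) < 2L) {
    return(excluded_patient("SOZ does not span two symmetrically covered regions"))
  }
  set_mean <- function(set) {
    sub <- regnet$adjacency[set, set, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  s <- set_mean(A_set)
  c_ <- set_mean(B_set)
  if (is.na(s) || is.na(c_)) return(excluded_patient("no defined intra-set edges"))
  list(soz = s, contra = c_)
}

#' Wilcoxon signed-rank test with positive-rank-sum statistic
#'
#' Paired signed-rank test reporting T+ (the sum of ranks of positive
#' differences, midranks for ties, zero differences dropped). The two-sided
#' p-value is exact for n <= 25 -- computed by dynamic programming over the
#' 2^n equally likely sign assignments, which handles midranks -- and a
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param x numeric vector: first member of each pair, or the differences
#'   themselves when `y` is NULL.
#' @param y optional second member of each pair.
#' @return list with `T_plus`, `p`, `n_used`, `n_zero`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences zero: test undefined")
    return(list(T_plus = NA_real_, p = NA_real_, n_used = 0L,
                n_zero = n_zero, method = "undefined"))
  }
  r <- rank(abs(d))
  T_plus <- sum(r[d > 0])
  if (n <= 25L) {
    w <- as.integer(round(2 * r))     # doubled ranks are integers even with midranks
    total <- sum(w)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (wi in w) {
      f[(wi + 1L):(total + 1L)] <- f[(wi + 1L):(total + 1L)] + f[1L:(total + 1L - wi)]
    }
    t2 <- as.integer(round(2 * T_plus))
    p_le <- sum(f[1L:(t2 + 1L)]) / 2^n
    p_ge <- sum(f[(t2 + 1L):(total + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (T_plus - mu - sign(T_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(T_plus = T_plus, p = p, n_used = n, n_zero = n_zero, method = method)
}

#' Cohort-level SOZ contrast
#'
#' Applies one of the three homotopic contrasts to every analyzed patient,
#' collects the per-patient (SOZ, contralateral) pairs with inclusion flags
#' and exclusion reasons, and runs the signed-rank test on the included
#' pairs.
#'
#' @param analyses list of per-patient analyses from [analyze_patient()].
#' @param patients list of patients (for laterality labels and ids).
#' @param atlas an [atlas_lookup()] table.
#' @param kind one of "regional", "intrahemispheric", "intrinsic".
#' @return list with `pairs` (data.frame: patient, soz, contra, included,
#'   reason) and `test` (the [wilcoxon_signed_rank()] result, or NULL when
#'   fewer than two pairs are included).
#' @export
cohort_contrast <- function(analyses, patients, atlas,
                            kind = c("regional", "intrahemispheric", "intrinsic")) {
  kind <- match.arg(kind)
  rows <- lapply(seq_along(analyses), function(i) {
    a <- analyses[[i]]
    p <- patients[[i]]
    res <- switch(kind,
      regional = soz_regional_connectivity(a$symmetric, a$soz_regions, atlas),
      intrahemispheric = intrahemispheric_connectivity(a$symmetric, p$laterality, atlas),
      intrinsic = intrinsic_soz_connectivity(a$symmetric, a$soz_regions, atlas))
    if (is_excluded(res)) {
      data.frame(patient = p$patient_id, soz = NA_real_, contra = NA_real_,
                 included = FALSE, reason = exclusion_reason(res) %||% "excluded",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient = p$patient_id, soz = res$soz, contra = res$contra,
                 included = TRUE, reason = "", stringsAsFactors = FALSE)
    }
  })
  pairs <- do.call(rbind, rows)
  inc <- pairs[pairs$included, , drop = FALSE]
  test <- if (nrow(inc) >= 2L) wilcoxon_signed_rank(inc$soz, inc$contra) else NULL
  list(pairs = pairs, test = test, kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
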