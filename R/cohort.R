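#' Synthetic cohort specification
#'
#' Collects the generator parameters that define the statistical structure of
#' a simulated intracranial-EEG cohort: coverage asymmetry, density-biased
#' stereo sampling near the seizure-onset zone (SOZ), a target inter-channel
#' correlation structure in which SOZ-involving edges are scaled down, and
#' hemisphere-lateralized spike rates.
#'
#' @param n_patients number of patients (>= 1).
#' @param fs sampling rate in Hz.
#' @param duration_s seconds of signal per patient.
#' @param n_regions_per_hemisphere homotopic region pairs in the synthetic atlas.
#' @param soz_conn_reduction fraction in \[0, 1\] by which correlations on
#'   SOZ-involving edges are scaled down (0 = null effect).
#' @param spike_rate_ratio expected ratio of SOZ-side to contralateral spike
#'   rates (>= 1; 1 = null effect).
#' @param stereo_fraction fraction of patients with stereo (density-biased)
#'   implants; the rest get uniformly spaced grid/strip/depth layouts.
#' @param bilateral_coverage_prob probability a region pair is covered in
#'   both hemispheres.
#' @param base_corr baseline inter-electrode correlation, in (0, 1).
#' @param conn_gain_sd log-scale SD of per-electrode connectivity gains
#'   (mean-1 lognormal), emulating electrode-level variability in broad
#'   connectivity; 0 gives the homogeneous structure of
#'   [sample_target_covariance()].
#' @param base_spike_rate baseline spike rate in events/min.
#' @param ar_phi AR(1) smoothing coefficient applied identically to every
#'   channel (preserves zero-lag correlations; 0 = white noise).
#' @param laterality_probs named probabilities for left/right/bilateral/none
#'   SOZ laterality.
#' @param seed RNG seed making the cohort reproducible.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 40L, fs = 256, duration_s = 600,
                        n_regions_per_hemisphere = 8L,
                        soz_conn_reduction = 0.5, spike_rate_ratio = 2,
                        stereo_fraction = 0.86, bilateral_coverage_prob = 0.5,
                        base_corr = 0.3, conn_gain_sd = 0.3,
                        base_spike_rate = 0.5, ar_phi = 0.5,
                        laterality_probs = c(left = 0.436, right = 0.30,
                                             bilateral = 0.227, none = 0.037),
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients), fs = fs,
               duration_s = duration_s,
               n_regions_per_hemisphere = as.integer(n_regions_per_hemisphere),
               soz_conn_reduction = soz_conn_reduction,
               spike_rate_ratio = spike_rate_ratio,
               stereo_fraction = stereo_fraction,
               bilateral_coverage_prob = bilateral_coverage_prob,
               base_corr = base_corr, conn_gain_sd = conn_gain_sd,
               base_spike_rate = base_spike_rate,
               ar_phi = ar_phi, laterality_probs = laterality_probs,
               seed = as.integer(seed))
  frac01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (spec$n_patients < 1L) stop("n_patients must be >= 1")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (spec$n_regions_per_hemisphere < 2L) stop("need >= 2 region pairs")
  if (!frac01(soz_conn_reduction)) stop("soz_conn_reduction must be in [0, 1]")
  if (spike_rate_ratio < 1) stop("spike_rate_ratio must be >= 1")
  if (!frac01(stereo_fraction)) stop("stereo_fraction must be in [0, 1]")
  if (!frac01(bilateral_coverage_prob)) stop("bilateral_coverage_prob must be in [0, 1]")
  if (base_corr <= 0 || base_corr >= 1) stop("base_corr must be in (0, 1)")
  if (conn_gain_sd < 0) stop("conn_gain_sd must be non-negative")
  if (base_spike_rate <= 0) stop("base_spike_rate must be positive")
  if (ar_phi < 0 || ar_phi >= 1) stop("ar_phi must be in [0, 1)")
  if (!setequal(names(laterality_probs), c("left", "right", "bilateral", "none")) ||
      any(laterality_probs < 0)) {
    stop("laterality_probs must name left/right/bilateral/none with non-negative values")
  }
  structure(spec, class = "cohort_spec")
}

#' Target inter-electrode covariance for signal synthesis
#'
#' Unit-diagonal matrix with every off-diagonal entry equal to `base_corr`,
#' except that entries involving an SOZ electrode are scaled by
#' `(1 - reduction)`. If the construction is not positive semi-definite it is
#' repaired by clipping negative eigenvalues and rescaling to unit diagonal
#' (flagged via the `"repaired"` attribute and a message).
#'
#' @param layout electrode table (data.frame) with a logical `soz_flag` column.
#' @param base_corr baseline correlation in (0, 1).
#' @param reduction fraction in \[0, 1\] applied to SOZ-involving edges.
#' @return symmetric positive semi-definite matrix with unit diagonal.
#' @export
sample_target_covariance <- function(layout, base_corr = 0.3, reduction = 0) {
  stopifnot(base_corr > 0, base_corr < 1, reduction >= 0, reduction <= 1)
  soz <- as.logical(layout$soz_flag)
  S <- build_target_covariance(matrix(base_corr, length(soz), length(soz)),
                               soz, reduction)
  if (attr(S, "repaired")) {
    message("target covariance repaired to nearest positive semi-definite")
  }
  S
}

# shared core: scale SOZ-involving entries of a base correlation matrix,
# set unit diagonal, repair to PSD by eigenvalue clipping if needed
build_target_covariance <- function(base_mat, soz, reduction) {
  S <- base_mat
  mask <- outer(soz, soz, "|")
  S[mask] <- S[mask] * (1 - reduction)
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 1e-8)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    repaired <- TRUE
  }
  attr(S, "repaired") <- repaired
  S
}

# correlated stationary Gaussian signals with exact zero-lag covariance Sigma
simulate_signals <- function(Sigma, n_samples, ar_phi = 0.5, amplitude = 50) {
  n <- nrow(Sigma)
  W <- matrix(stats::rnorm(n * n_samples), n, n_samples)
  if (ar_phi > 0) {
    for (ch in seq_len(n)) {
      W[ch, ] <- as.numeric(stats::filter(W[ch, ], ar_phi, method = "recursive"))
    }
    W <- W * sqrt(1 - ar_phi^2)  # restore unit stationary variance
  }
  amplitude * (t(chol(Sigma)) %*% W)
}

simulate_patient <- function(spec, atlas, patient_id) {
  n_pairs <- spec$n_regions_per_hemisphere
  pair_left <- atlas$region_id[atlas$hemisphere == "left"]
  pair_right <- homotopic_regions(atlas, pair_left)
  lat <- sample(names(spec$laterality_probs), 1L, prob = spec$laterality_probs)
  implant <- if (stats::runif(1) < spec$stereo_fraction) "stereo" else "grid-strip-depth"

  covered <- matrix(FALSE, n_pairs, 2, dimnames = list(NULL, c("left", "right")))
  for (k in seq_len(n_pairs)) {
    if (stats::runif(1) < spec$bilateral_coverage_prob) {
      covered[k, ] <- TRUE
    } else if (stats::runif(1) < 0.5) {
      covered[k, sample(2L, 1L)] <- TRUE
    }
  }

  # SOZ target pairs: chosen uniformly (anatomy-neutral) and forced to
  # bilateral coverage -- implantation follows the pre-implant hypothesis,
  # including the contralateral homologue for comparison
  soz_regions <- character(0)
  soz_sides <- character(0)
  if (lat != "none") {
    targets <- sample(n_pairs, 2L)
    covered[targets, ] <- TRUE
    if (lat == "left") {
      soz_regions <- pair_left[targets]
      soz_sides <- "left"
    } else if (lat == "right") {
      soz_regions <- pair_right[targets]
      soz_sides <- "right"
    } else {
      soz_regions <- c(pair_left[targets[1]], pair_right[targets[2]])
      soz_sides <- c("left", "right")
    }
  }

  rows <- list()
  for (k in seq_len(n_pairs)) {
    for (side in c("left", "right")) {
      if (!covered[k, side]) next
      rid <- if (side == "left") pair_left[k] else pair_right[k]
      arow <- atlas[atlas$region_id == rid, ]
      is_soz_region <- rid %in% soz_regions
      n_e <- 2L
      jitter_sd <- 5
      if (implant == "stereo" && is_soz_region) {
        n_e <- 5L          # denser, tighter sampling at the hypothesized SOZ
        jitter_sd <- 2.5
      }
      if (implant == "grid-strip-depth") {
        offs <- (seq_len(n_e) - (n_e + 1) / 2) * 8   # uniform 8 mm pitch
        xyz <- cbind(arow$x, arow$y + offs, arow$z)
      } else {
        xyz <- cbind(arow$x + stats::rnorm(n_e, 0, jitter_sd),
                     arow$y + stats::rnorm(n_e, 0, jitter_sd),
                     arow$z + stats::rnorm(n_e, 0, jitter_sd))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s-%d", rid, seq_len(n_e)),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        region_id = rid, coarse_anatomy = arow$coarse_anatomy,
        hemisphere = arow$hemisphere, soz_flag = is_soz_region,
        stringsAsFactors = FALSE)
    }
  }
  etab <- do.call(rbind, rows)
  rownames(etab) <- NULL

  # hemisphere-lateralized spike rates, concentrated at SOZ electrodes: the
  # SOZ-side mean is exactly ratio x baseline, with one third of the
  # elevation spread over the side and the rest focal to SOZ electrodes
  rate <- rep(spec$base_spike_rate, nrow(etab))
  r <- spec$spike_rate_ratio
  for (side in soz_sides) {
    on_side <- etab$hemisphere == side
    is_soz <- on_side & etab$soz_flag
    n_s <- sum(is_soz)
    n_o <- sum(on_side) - n_s
    r_b <- 1 + (r - 1) / 3
    r_e <- if (n_s > 0L) ((n_s + n_o) * r - n_o * r_b) / n_s else r
    rate[on_side & !etab$soz_flag] <- spec$base_spike_rate * r_b
    rate[is_soz] <- spec$base_spike_rate * r_e
  }
  spikes <- stats::rgamma(nrow(etab), shape = 20, rate = 20 / rate)
  names(spikes) <- etab$name

  # per-electrode connectivity gains: lognormal, mean 1; SOZ scaling is
  # applied to the (capped) heterogeneous base so the reduction stays exact
  n_el <- nrow(etab)
  if (spec$conn_gain_sd > 0) {
    g <- stats::rlnorm(n_el, -spec$conn_gain_sd^2 / 2, spec$conn_gain_sd)
    base_mat <- pmin(spec$base_corr * outer(g, g), 0.9)
  } else {
    base_mat <- matrix(spec$base_corr, n_el, n_el)
  }
  Sigma <- build_target_covariance(base_mat, etab$soz_flag,
                                   spec$soz_conn_reduction)
  sig <- simulate_signals(Sigma, round(spec$duration_s * spec$fs), spec$ar_phi)
  rec <- recording(sig, spec$fs, channel_names = etab$name)

  structure(list(patient_id = patient_id, electrode_table = etab,
                 recording = rec, spike_rates = spikes, laterality = lat,
                 implant_type = implant, soz_regions = soz_regions,
                 target_covariance = Sigma),
            class = "synthetic_patient")
}

#' Generate a synthetic cohort
#'
#' Simulates `spec$n_patients` patients sharing one synthetic bilateral
#' atlas. Each patient gets: a laterality label; asymmetric region coverage
#' (bilateral with probability `bilateral_coverage_prob`); two SOZ region
#' pairs forced to bilateral coverage when a SOZ exists; stereo layouts with
#' denser, tighter electrode placement in SOZ regions (grid layouts keep
#' uniform 8 mm spacing); zero-mean stationary Gaussian signals whose target
#' correlation scales SOZ-involving edges by `(1 - soz_conn_reduction)`; and
#' spike rates elevated by `spike_rate_ratio` on the SOZ side. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return an `ieeg_cohort`: list with `patients`, the shared `atlas`, and
#'   the generating `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  atlas <- synthetic_atlas(spec$n_regions_per_hemisphere)
  ids <- sprintf("P%03d", seq_len(spec$n_patients))
  patients <- lapply(ids, function(id) simulate_patient(spec, atlas, id))
  structure(list(patients = patients, atlas = atlas, spec = spec),
            class = "ieeg_cohort")
}

#' Write a cohort to disk as portable text/array files
#'
#' Per patient: the electrode table and spike rates as CSV, and the signal
#' matrix as Feather (when the arrow package is available) or CSV. A cohort
#' manifest (YAML) records patient files, labels, the atlas path and the
#' generating parameters.
#'
#' @param cohort an `ieeg_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(unclass(cohort$atlas)),
                   file.path(dir, "atlas.csv"), row.names = FALSE)
  use_arrow <- requireNamespace("arrow", quietly = TRUE)
  entries <- list()
  for (p in cohort$patients) {
    pd <- file.path(dir, p$patient_id)
    dir.create(pd, showWarnings = FALSE)
    utils::write.csv(p$electrode_table, file.path(pd, "electrodes.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(name = names(p$spike_rates),
                                spike_rate = as.numeric(p$spike_rates)),
                     file.path(pd, "spike_rates.csv"), row.names = FALSE)
    sig <- as.data.frame(t(p$recording$signal))
    names(sig) <- p$recording$channel_names
    if (use_arrow) {
      sig_file <- file.path(pd, "signals.feather")
      arrow::write_feather(sig, sig_file)
    } else {
      sig_file <- file.path(pd, "signals.csv")
      utils::write.csv(sig, sig_file, row.names = FALSE)
    }
    entries[[p$patient_id]] <- list(
      dir = p$patient_id, laterality = p$laterality,
      implant_type = p$implant_type, fs = p$recording$fs,
      signals = basename(sig_file))
  }
  manifest <- list(atlas = "atlas.csv", seed = cohort$spec$seed,
                   parameters = unclass(cohort$spec)[
                     c("n_patients", "fs", "duration_s", "soz_conn_reduction",
                       "spike_rate_ratio", "stereo_fraction",
                       "bilateral_coverage_prob", "base_corr")],
                   patients = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
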