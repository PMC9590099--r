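#' Atlas lookup table
#'
#' Constructs and validates the parcellation lookup used for nearest-region
#' electrode assignment and homotopic (left/right) pairing. The atlas is a
#' plain table, one row per hemisphere-specific parcel, with a representative
#' centroid for distance computations and a coarse anatomical class used by
#' the spatial null model.
#'
#' @param df data.frame with columns `region_id`, `hemisphere`
#'   ("left"/"right"/"none"), `homotopic_id`, `coarse_anatomy` (one of
#'   "mesial temporal", "temporal neocortical", "other cortex", "excluded"),
#'   and centroid coordinates `x`, `y`, `z` (mm).
#' @return the validated data.frame with class `atlas_lookup`.
#' @export
atlas_lookup <- function(df) {
  needed <- c("region_id", "hemisphere", "homotopic_id", "coarse_anatomy",
              "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("atlas table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("atlas table is empty")
  if (anyDuplicated(df$region_id)) stop("duplicate region_id in atlas")
  # homotopic pairing must be an involution across hemispheres
  paired <- !is.na(df$homotopic_id)
  idx <- match(df$homotopic_id[paired], df$region_id)
  if (anyNA(idx)) stop("homotopic_id refers to unknown region")
  back <- df$homotopic_id[idx]
  if (!all(back == df$region_id[paired])) {
    stop("homotopic pairing is not an involution")
  }
  if (any(df$hemisphere[paired] == df$hemisphere[idx])) {
    stop("homotopic partners must lie in opposite hemispheres")
  }
  df <- df[order(df$region_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("atlas_lookup", "data.frame")
  df
}

#' Homotopic partners of a set of regions
#'
#' @param atlas an [atlas_lookup()] table.
#' @param regions character vector of region ids.
#' @return character vector of contralateral partner ids (NA when unpaired).
#' @export
homotopic_regions <- function(atlas, regions) {
  atlas$homotopic_id[match(regions, atlas$region_id)]
}

#' Synthetic bilateral atlas
#'
#' Builds a deterministic toy parcellation with `n_pairs` homotopic region
#' pairs laid out along the anterior-posterior axis, mirrored across the
#' midline (x = 0). Roughly a quarter of pairs are labelled mesial temporal
#' and placed nearer the midline, a sixth temporal neocortical, the rest
#' other cortex -- enough anatomical structure to exercise the coarse-anatomy
#' predictors without any imaging dependency.
#'
#' @param n_pairs number of homotopic region pairs per hemisphere.
#' @return an [atlas_lookup()] table with `2 * n_pairs` rows.
#' @export
synthetic_atlas <- function(n_pairs = 8L) {
  n_pairs <- as.integer(n_pairs)
  stopifnot(n_pairs >= 1L)
  y <- seq(-60, 60, length.out = n_pairs)
  z <- rep(c(-20, 0, 20), length.out = n_pairs)
  n_mt <- max(1L, round(0.25 * n_pairs))
  n_tn <- if (n_pairs >= 3L) max(1L, round(0.15 * n_pairs)) else 0L
  coarse <- rep("other cortex", n_pairs)
  coarse[seq_len(n_mt)] <- "mesial temporal"
  if (n_tn > 0L) coarse[n_mt + seq_len(n_tn)] <- "temporal neocortical"
  x <- ifelse(coarse == "mesial temporal", 25, 45)
  lid <- sprintf("L%02d", seq_len(n_pairs))
  rid <- sprintf("R%02d", seq_len(n_pairs))
  left <- data.frame(region_id = lid, hemisphere = "left", homotopic_id = rid,
                     coarse_anatomy = coarse, x = -x, y = y, z = z,
                     stringsAsFactors = FALSE)
  right <- data.frame(region_id = rid, hemisphere = "right", homotopic_id = lid,
                      coarse_anatomy = coarse, x = x, y = y, z = z,
                      stringsAsFactors = FALSE)
  atlas_lookup(rbind(left, right))
}

#' Assign electrodes to nearest atlas regions
#'
#' Each electrode receives the region whose representative centroid minimizes
#' Euclidean distance; ties break deterministically to the smallest
#' `region_id`. Electrodes farther than `max_dist` from every centroid are
#' labelled `"excluded"` (outside the parcellation, e.g. white matter).
#'
#' @param electrodes data.frame with columns `x`, `y`, `z` (same space as the
#'   atlas centroids).
#' @param atlas an [atlas_lookup()] table.
#' @param max_dist maximum assignment distance in mm; beyond it an electrode
#'   is labelled excluded.
#' @return character vector of region labels, one per electrode.
#' @export
assign_regions <- function(electrodes, atlas, max_dist = 20) {
  if (nrow(atlas) == 0L) stop("empty atlas")
  stopifnot(all(c("x", "y", "z") %in% names(electrodes)))
  coords <- as.matrix(electrodes[, c("x", "y", "z")])
  cents <- as.matrix(atlas[, c("x", "y", "z")])
  # atlas rows are sorted by region_id, so which.min's first match is the tie-break
  labels <- character(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    d2 <- colSums((t(cents) - coords[i, ])^2)
    j <- which.min(d2)
    labels[i] <- if (sqrt(d2[j]) > max_dist) "excluded" else atlas$region_id[j]
  }
  labels
}

#' Region-level network from an electrode network
#'
#' Aggregates an electrode-level functional network onto atlas regions: the
#' edge between regions i and j (i != j) is the mean connectivity over all
#' electrode pairs spanning the two regions. Diagonal entries (within-region
#' connectivity) are left undefined, so all downstream averages study
#' inter-regional connections only. Region spike rates, when electrode spike
#' rates are supplied, are the mean over member electrodes.
#'
#' @param net a `functional_network` (see [pearson_network()]).
#' @param labels region label per electrode ("excluded" electrodes are dropped).
#' @param spike_rates optional numeric vector of per-electrode spike rates
#'   (events/min), aligned with the network channels.
#' @return a `region_network`: list with `adjacency` (region x region, NA
#'   diagonal), `regions`, `coverage` (electrode counts), `spike_rates`
#'   (per-region means or NULL), and the electrode `labels` used.
#' @export
region_network <- function(net, labels, spike_rates = NULL) {
  adj <- net$adjacency
  stopifnot(length(labels) == nrow(adj))
  keep <- labels != "excluded" & !is.na(labels)
  regions <- sort(unique(labels[keep]))
  if (length(regions) < 1L) stop("no labelled electrodes")
  k <- length(regions)
  A <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  members <- lapply(regions, function(r) which(labels == r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      vals <- adj[members[[i]], members[[j]], drop = FALSE]
      if (any(!is.na(vals))) {
        A[i, j] <- A[j, i] <- mean(vals, na.rm = TRUE)
      }
    }
  }
  coverage <- vapply(members, length, integer(1))
  names(coverage) <- regions
  reg_spikes <- NULL
  if (!is.null(spike_rates)) {
    stopifnot(length(spike_rates) == length(labels))
    reg_spikes <- vapply(members, function(m) mean(spike_rates[m]), numeric(1))
    names(reg_spikes) <- regions
  }
  structure(list(adjacency = A, regions = regions, coverage = coverage,
                 spike_rates = reg_spikes, labels = labels),
            class = "region_network")
}

#' Restrict a region network to symmetric (bilateral) coverage
#'
#' Retains exactly those covered regions whose homotopic partner is also
#' covered; every edge touching a removed region becomes undefined. The
#' retained set is closed under homotopic pairing by construction, which is
#' what makes hemisphere-to-hemisphere contrasts fair: both sides see the
#' same parcels.
#'
#' @param regnet a [region_network()].
#' @param atlas an [atlas_lookup()] table providing the pairing.
#' @return the region network with a `retained` character vector and all
#'   edges outside `retained` set to NA.
#' @export
symmetric_coverage <- function(regnet, atlas) {
  covered <- regnet$regions[regnet$coverage > 0L]
  partners <- homotopic_regions(atlas, covered)
  retained <- covered[!is.na(partners) & partners %in% covered]
  A <- regnet$adjacency
  drop <- setdiff(rownames(A), retained)
  A[drop, ] <- NA_real_
  A[, drop] <- NA_real_
  regnet$adjacency <- A
  regnet$retained <- retained
  regnet
}

#' Coverage-balanced region network by electrode subsampling
#'
#' Controls for unequal electrode counts between a region and its homotopic
#' partner: in each of `n_resamples` draws, every retained region's electrode
#' set is randomly reduced to min(own count, contralateral count), the region
#' network is recomputed, and the output is the element-wise mean across
#' draws. When all counts are already balanced every draw is the full set and
#' the result equals the unsubsampled network exactly.
#'
#' @param net electrode-level `functional_network`.
#' @param labels region label per electrode.
#' @param atlas an [atlas_lookup()] table.
#' @param n_resamples number of random subsampling draws.
#' @param seed optional RNG seed for reproducibility.
#' @param spike_rates optional per-electrode spike rates, averaged the same way.
#' @return a symmetric-coverage `region_network` averaged over draws.
#' @export
subsample_balance <- function(net, labels, atlas, n_resamples = 100,
                              seed = NULL, spike_rates = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- region_network(net, labels, spike_rates = spike_rates)
  base <- symmetric_coverage(base, atlas)
  retained <- base$retained
  if (length(retained) == 0L) return(base)
  counts <- base$coverage[retained]
  partner <- homotopic_regions(atlas, retained)
  target <- pmin(counts, base$coverage[partner])
  target[is.na(target)] <- counts[is.na(target)]
  if (all(target == counts)) return(base)  # balanced: every draw is the full set
  k <- length(retained)
  A_sum <- matrix(0, k, k, dimnames = list(retained, retained))
  A_cnt <- matrix(0L, k, k)
  s_sum <- if (!is.null(spike_rates)) stats::setNames(numeric(k), retained) else NULL
  for (b in seq_len(n_resamples)) {
    labs <- labels
    for (r in retained) {
      m <- which(labels == r)
      if (length(m) > target[[r]]) {
        drop <- sample(m, length(m) - target[[r]])
        labs[drop] <- "excluded"
      }
    }
    labs[!(labs %in% retained)] <- "excluded"
    rn <- region_network(net, labs, spike_rates = spike_rates)
    Ab <- rn$adjacency[retained, retained]
    ok <- !is.na(Ab)
    A_sum[ok] <- A_sum[ok] + Ab[ok]
    A_cnt <- A_cnt + ok
    if (!is.null(s_sum)) s_sum <- s_sum + rn$spike_rates[retained]
  }
  A <- A_sum / A_cnt
  A[A_cnt == 0L] <- NA_real_
  base$adjacency[] <- NA_real_
  base$adjacency[retained, retained] <- A
  base$coverage[retained] <- target
  if (!is.null(s_sum)) base$spike_rates[retained] <- s_sum / n_resamples
  base$n_resamples <- n_resamples
  base
}
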