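# Shared fixtures, built in code.

# a recording of independent white noise
noise_recording <- function(n_chan = 3, seconds = 30, fs = 256, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n_chan * seconds * fs), n_chan), fs)
}

# minimal two-pair atlas: L01/R01 (mesial temporal), L02/R02 (other cortex)
tiny_atlas <- function() {
  atlas_lookup(data.frame(
    region_id = c("L01", "L02", "R01", "R02"),
    hemisphere = c("left", "left", "right", "right"),
    homotopic_id = c("R01", "R02", "L01", "L02"),
    coarse_anatomy = c("mesial temporal", "other cortex",
                       "mesial temporal", "other cortex"),
    x = c(-25, -45, 25, 45), y = c(0, 20, 0, 20), z = c(0, 0, 0, 0),
    stringsAsFactors = FALSE))
}

# functional network with explicitly given edges
edge_network <- function(adj, names = NULL) {
  if (is.null(names)) names <- paste0("e", seq_len(nrow(adj)))
  dimnames(adj) <- list(names, names)
  diag(adj) <- NA_real_
  structure(list(adjacency = adj, metric = "pearson", band = "broadband",
                 n_windows_used = matrix(1L, nrow(adj), ncol(adj)),
                 channel_names = names),
            class = "functional_network")
}

# symmetric-coverage region network built directly from a region adjacency
region_net_from_adj <- function(adj, atlas, coverage = NULL) {
  regions <- rownames(adj)
  diag(adj) <- NA_real_
  if (is.null(coverage)) coverage <- setNames(rep(1L, length(regions)), regions)
  rn <- structure(list(adjacency = adj, regions = regions, coverage = coverage,
                       spike_rates = NULL, labels = NULL),
                  class = "region_network")
  symmetric_coverage(rn, atlas)
}

# brute-force Wilcoxon T+ and exact two-sided p by full sign enumeration
enumerate_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  T_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ts <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(Ts <= T_obs)
  p_ge <- mean(Ts >= T_obs)
  list(T_plus = T_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# direct-summation kernel density oracle (double loop over the equation)
kernel_density_oracle <- function(coords, radius = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  if (is.null(radius)) radius <- max(D)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- D[i, j]
      if (dij > radius) next
      acc <- acc + (3 / pi) * (1 - (dij / radius)^2)^2
    }
    out[i] <- acc / radius^2
  }
  out
}

small_test_cohort <- function(n_patients = 8, seed = 5, ...) {
  generate_cohort(cohort_spec(n_patients = n_patients, duration_s = 30,
                              seed = seed, ...))
}
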