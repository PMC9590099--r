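test_that("atlas validation catches malformed pairing", {
  bad <- data.frame(region_id = c("L01", "R01"), hemisphere = c("left", "left"),
                    homotopic_id = c("R01", "L01"),
                    coarse_anatomy = "other cortex",
                    x = c(-1, 1), y = 0, z = 0)
  expect_error(atlas_lookup(bad), "opposite hemispheres")
  bad2 <- data.frame(region_id = c("L01", "R01"), hemisphere = c("left", "right"),
                     homotopic_id = c("R01", "R01"),
                     coarse_anatomy = "other cortex",
                     x = c(-1, 1), y = 0, z = 0)
  expect_error(atlas_lookup(bad2), "involution")
  expect_error(atlas_lookup(data.frame(x = 1)), "lacks columns")
})

test_that("synthetic atlas pairing is an involution across hemispheres", {
  atlas <- synthetic_atlas(8)
  expect_identical(nrow(atlas), 16L)
  back <- homotopic_regions(atlas, homotopic_regions(atlas, atlas$region_id))
  expect_identical(back, atlas$region_id)
})

test_that("electrodes are assigned to the nearest region with deterministic ties", {
  atlas <- tiny_atlas()
  at_centroid <- data.frame(x = -25, y = 0, z = 0)
  expect_identical(assign_regions(at_centroid, atlas), "L01")

  equidistant <- data.frame(x = 0, y = 0, z = 0)  # L01 and R01 tie
  expect_identical(assign_regions(equidistant, atlas, max_dist = Inf), "L01")

  far <- data.frame(x = 500, y = 0, z = 0)
  expect_identical(assign_regions(far, atlas), "excluded")

  set.seed(13)
  atlas8 <- synthetic_atlas(8)
  pts <- data.frame(x = runif(50, -60, 60), y = runif(50, -70, 70),
                    z = runif(50, -30, 30))
  got <- assign_regions(pts, atlas8, max_dist = Inf)
  cents <- as.matrix(atlas8[, c("x", "y", "z")])
  oracle <- vapply(seq_len(50), function(i) {
    d <- sqrt(colSums((t(cents) - as.numeric(pts[i, ]))^2))
    atlas8$region_id[which.min(d)]
  }, character(1))
  expect_identical(got, oracle)
})

test_that("region networks average electrode pairs and leave the diagonal unknown", {
  adj <- matrix(NA_real_, 3, 3)
  adj[1, 3] <- adj[3, 1] <- 0.2
  adj[2, 3] <- adj[3, 2] <- 0.4
  adj[1, 2] <- adj[2, 1] <- 0.9
  net <- edge_network(adj)
  rn <- region_network(net, c("A", "A", "B"))
  expect_equal(rn$adjacency["A", "B"], 0.3)
  expect_true(is.na(rn$adjacency["A", "A"]))
  expect_equal(unname(rn$coverage), c(2L, 1L))

  rn2 <- region_network(net, c("A", "excluded", "B"))
  expect_equal(rn2$adjacency["A", "B"], 0.2)

  spikes <- c(3, 5, 10)
  rn3 <- region_network(net, c("A", "A", "B"), spike_rates = spikes)
  expect_equal(unname(rn3$spike_rates), c(4, 10))
})

test_that("region aggregation matches a brute-force double loop on random inputs", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    m <- matrix(runif(n * n, -1, 1), n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    rn <- region_network(edge_network(m), labels)
    for (a in unique(labels)) {
      for (b in unique(labels)) {
        if (a >= b) next
        vals <- c()
        for (i in which(labels == a)) {
          for (j in which(labels == b)) vals <- c(vals, m[i, j])
        }
        expect_equal(rn$adjacency[a, b], mean(vals))
      }
    }
  }
})

test_that("region edges lie within the range of contributing electrode edges", {
  set.seed(29)
  n <- 10
  m <- matrix(runif(n * n, -1, 1), n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  labels <- rep(c("A", "B"), each = 5)
  rn <- region_network(edge_network(m), labels)
  cross <- m[1:5, 6:10]
  expect_gte(rn$adjacency["A", "B"], min(cross))
  expect_lte(rn$adjacency["A", "B"], max(cross))
})

test_that("symmetric coverage retains exactly the bilaterally covered pairs", {
  atlas <- tiny_atlas()
  adj <- matrix(0.5, 3, 3)
  dimnames(adj) <- list(c("L01", "L02", "R01"), c("L01", "L02", "R01"))
  rn <- region_net_from_adj(adj, atlas)
  expect_setequal(rn$retained, c("L01", "R01"))
  expect_true(all(is.na(rn$adjacency["L02", ])))
  expect_false(is.na(rn$adjacency["L01", "R01"]))

  # fully bilateral coverage is the identity
  adj4 <- matrix(0.3, 4, 4)
  dimnames(adj4) <- list(atlas$region_id, atlas$region_id)
  rn4 <- region_net_from_adj(adj4, atlas)
  expect_setequal(rn4$retained, atlas$region_id)
  off <- !is.na(rn4$adjacency)
  expect_true(all(rn4$adjacency[off] == 0.3))
})

test_that("symmetric coverage is closed under homotopic pairing on random patterns", {
  atlas <- synthetic_atlas(6)
  set.seed(37)
  for (rep in 1:200) {
    covered <- sample(atlas$region_id, sample(2:10, 1))
    k <- length(covered)
    adj <- matrix(runif(k * k), k, dimnames = list(covered, covered))
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    rn <- region_net_from_adj(adj, atlas)
    partners <- homotopic_regions(atlas, rn$retained)
    expect_true(all(partners %in% rn$retained))
    # oracle: set-based rule
    oracle <- covered[homotopic_regions(atlas, covered) %in% covered]
    expect_setequal(rn$retained, oracle)
  }
})

test_that("subsampling is the identity when counts are balanced", {
  atlas <- tiny_atlas()
  set.seed(41)
  m <- matrix(runif(36, -1, 1), 6)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  labels <- c("L01", "L01", "R01", "R01", "L02", "R02")
  net <- edge_network(m)
  plain <- symmetric_coverage(region_network(net, labels), atlas)
  sub <- subsample_balance(net, labels, atlas, n_resamples = 5, seed = 1)
  expect_identical(sub$adjacency, plain$adjacency)
})

test_that("subsampling a 2-vs-1 region converges to the subset-enumeration mean", {
  atlas <- tiny_atlas()
  m <- matrix(0, 4, 4)
  # L01 has electrodes 1,2; R01 has 3; L02 -> 4 unmatched (dropped)
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.8
  net <- edge_network(m)
  labels <- c("L01", "L01", "R01", "L02")
  sub <- subsample_balance(net, labels, atlas, n_resamples = 2000, seed = 7)
  # exact enumeration: each single-electrode choice occurs with prob 1/2
  expect_equal(sub$adjacency["L01", "R01"], 0.5, tolerance = 0.03)
  expect_identical(unname(sub$coverage[c("L01", "R01")]), c(1L, 1L))

  s1 <- subsample_balance(net, labels, atlas, n_resamples = 50, seed = 3)
  s2 <- subsample_balance(net, labels, atlas, n_resamples = 50, seed = 3)
  expect_identical(s1$adjacency, s2$adjacency)  # seeded determinism
})
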