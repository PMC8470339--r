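test_that("site_distance_matrix reproduces hand-computed entries", {
  tr <- tree4()
  comm <- rbind(w1 = c(1L, 1L, 0L, 0L), w2 = c(0L, 0L, 1L, 1L), w3 = c(1L, 1L, 0L, 0L))
  colnames(comm) <- tr$tip.label
  for (metric in c("mntd", "mpd")) {
    m <- site_distance_matrix(tr, comm, metric = metric)
    expect_equal(unname(m["w1", "w2"]), 4)   # all cross distances are 4
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
  mn <- site_distance_matrix(tr, comm, metric = "mntd")
  expect_equal(unname(mn["w1", "w3"]), 0)    # identical sites
})

test_that("pcoa recovers a known Euclidean configuration to 1e-9", {
  set.seed(4)
  pts <- matrix(rnorm(28 * 2), 28, 2)
  d <- as.matrix(dist(pts))
  res <- pcoa_ord(d)
  expect_s3_class(res, "pcoa_result")
  rec <- as.matrix(dist(res$coordinates))
  expect_lt(max(abs(rec - d)), 1e-9)
  expect_equal(res$eigenvalues, sort(res$eigenvalues, decreasing = TRUE))
  expect_true(all(res$variance_explained >= 0))
  expect_lte(sum(res$variance_explained), 1 + 1e-12)
})

test_that("degenerate configurations behave as documented", {
  # three collinear points, distances 1, 1, 2: one axis carries everything
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  res <- pcoa_ord(d)
  expect_equal(variance_explained(res, 1), 1)
  # all-zero matrix: no positive axes at all
  z <- matrix(0, 4, 4)
  rz <- pcoa_ord(z)
  expect_length(rz$variance_explained, 0)
  expect_equal(ncol(rz$coordinates), 0)
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("variance_explained is monotone, bounded, and guards its arguments", {
  set.seed(8)
  cfg <- synth_config(n_tips = 60, n_sites = 12, richness_range = c(5, 15), seed = 8)
  tr <- generate_tree(cfg)
  comm <- generate_communities(tr, cfg)
  res <- pcoa_ord(site_distance_matrix(tr, comm, "mntd"))
  ks <- seq_along(res$variance_explained)
  cum <- vapply(ks, function(k) variance_explained(res, k), numeric(1))
  expect_true(all(diff(cum) >= -1e-12))
  expect_lte(max(cum), 1 + 1e-12)
  expect_equal(cum[length(ks)], 1)  # positive-eigenvalue denominator
  expect_error(variance_explained(res, 0), "positive")
  expect_error(variance_explained(res, length(ks) + 1), "exceeds")
})

test_that("pcoa is invariant to point ordering up to axis sign conventions", {
  set.seed(15)
  pts <- matrix(rnorm(10 * 3), 10, 3)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(letters[1:10], letters[1:10])
  perm <- sample(10)
  r1 <- pcoa_ord(d)
  r2 <- pcoa_ord(d[perm, perm])
  expect_equal(r1$eigenvalues, r2$eigenvalues, tolerance = 1e-9)
  expect_equal(as.matrix(dist(r1$coordinates))[rownames(d)[perm], rownames(d)[perm]],
               as.matrix(dist(r2$coordinates)), tolerance = 1e-9)
})

test_that("Lingoes and Cailliez corrections agree with the ape reference on non-Euclidean input", {
  set.seed(23)
  cfg <- synth_config(n_tips = 50, n_sites = 10, richness_range = c(4, 12), seed = 23)
  tr <- generate_tree(cfg)
  comm <- generate_communities(tr, cfg)
  d <- site_distance_matrix(tr, comm, "mntd")
  expect_lt(min(pcoa_ord(d)$eigenvalues), -1e-6)  # genuinely non-Euclidean input
  for (corr in c("lingoes", "cailliez")) {
    ours <- pcoa_ord(d, correction = corr)
    ref <- ape::pcoa(as.dist(d), correction = corr)
    ref_eig <- sort(ref$values$Corr_eig, decreasing = TRUE)
    ev <- sort(ours$eigenvalues, decreasing = TRUE)
    expect_equal(ev[seq_len(min(5, length(ev)))],
                 ref_eig[seq_len(min(5, length(ev)))], tolerance = 1e-6)
    # the corrected matrix is (near-)Euclidean: negligible negative mass
    expect_gt(min(ours$eigenvalues) / max(ours$eigenvalues), -1e-6)
  }
})
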