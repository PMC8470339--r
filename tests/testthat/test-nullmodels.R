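test_that("sample_null draws the right number of distinct species, reproducibly", {
  pool <- sprintf("sp%02d", 1:10)
  set.seed(1); s1 <- sample_null(pool, 4)
  expect_length(s1, 4)
  expect_false(anyDuplicated(s1) > 0)
  expect_true(all(s1 %in% pool))
  set.seed(1); expect_identical(sample_null(pool, 4), s1)
  expect_setequal(sample_null(pool, 10), pool)
  expect_error(sample_null(pool, 11), "exceeds pool size")
  expect_error(sample_null(pool, 0), ">= 1")
  set.seed(2)
  w <- c(rep(1, 9), 0)
  expect_false("sp10" %in% sample_null(pool, 5, weights = w))
})

test_that("ses implements the printed formula, including the NTI sign flip", {
  null1 <- c(2, 3, 4)  # mean 3, sd 1
  expect_equal(ses(5, null1), 2)
  expect_equal(ses(3, null1), 0)
  null2 <- c(2.5, 3, 3.5)  # mean 3, sd 0.5
  expect_equal(ses(2, null2, negate = TRUE), 2)
  # NTI is exactly the negative SES of MNTD by construction
  set.seed(9)
  for (i in 1:20) {
    nv <- rnorm(30); ob <- rnorm(1)
    expect_equal(ses(ob, nv, negate = TRUE), -ses(ob, nv))
  }
  err <- tryCatch(ses(4, rep(2, 10)), commphylo_undefined_ses = function(e) e)
  expect_s3_class(err, "commphylo_undefined_ses")
  expect_equal(err$observed, 4)
  expect_equal(err$null_mean, 2)
})

test_that("pdi_nti_report is bit-reproducible and robust to appending sites", {
  cfg <- synth_config(n_tips = 50, n_sites = 8, richness_range = c(4, 12), seed = 21)
  tr <- generate_tree(cfg)
  comm <- generate_communities(tr, cfg)
  r1 <- pdi_nti_report(tr, comm, reps = 99, seed = 5)
  r2 <- pdi_nti_report(tr, comm, reps = 99, seed = 5)
  expect_identical(r1, r2)
  expect_identical(r1$richness, as.integer(rowSums(comm)))
  # appending a site leaves earlier sites' values untouched (per-site substreams)
  extra <- rbind(comm, site99 = comm[1, ])
  rownames(extra) <- c(rownames(comm), "site99")
  r3 <- pdi_nti_report(tr, extra, reps = 99, seed = 5)
  expect_identical(r3$pdi[seq_len(nrow(comm))], r1$pdi)
  expect_identical(r3$nti[seq_len(nrow(comm))], r1$nti)
})

test_that("degenerate sites are reported as missing with a reason", {
  tr <- tree4()
  # site 'all' holds the entire pool: every null draw is identical -> sd 0
  comm <- rbind(all = c(1L, 1L, 1L, 1L), two = c(1L, 1L, 0L, 0L))
  colnames(comm) <- tr$tip.label
  rep <- pdi_nti_report(tr, comm, reps = 25, seed = 3)
  expect_true(is.na(rep$pdi[1]) && is.na(rep$nti[1]))
  expect_match(rep$note[1], "null sd is 0")
  # richness-1 site: NTI undefined, PDI still reported (root-to-tip depths
  # differ on this non-ultrametric tree, so the PD null has positive sd)
  tr2 <- parse_newick("((A:1,B:2):1,(C:3,D:4):1);")
  comm2 <- rbind(one = c(1L, 0L, 0L, 0L), rest = c(0L, 1L, 1L, 1L))
  colnames(comm2) <- tr2$tip.label
  rep2 <- pdi_nti_report(tr2, comm2, reps = 25, seed = 3)
  expect_true(is.na(rep2$nti[1]))
  expect_match(rep2$note[1], "richness < 2")
  expect_false(is.na(rep2$pdi[1]))
})

test_that("PDI is invariant to tree-preserving species relabeling", {
  cfg <- synth_config(n_tips = 40, n_sites = 5, richness_range = c(4, 10), seed = 13)
  tr <- generate_tree(cfg)
  comm <- generate_communities(tr, cfg)
  r1 <- pdi_nti_report(tr, comm, reps = 49, seed = 2)
  relab <- setNames(sprintf("x%03d", seq_along(tr$tip.label)), tr$tip.label)
  tr2 <- tr; tr2$tip.label <- unname(relab[tr$tip.label])
  comm2 <- comm; colnames(comm2) <- unname(relab[colnames(comm)])
  r2 <- pdi_nti_report(tr2, comm2, reps = 49, seed = 2)
  expect_equal(r2$pdi, r1$pdi)
  expect_equal(r2$nti, r1$nti)
})

test_that("report errors on unaligned tables and undersized pools", {
  tr <- tree4()
  comm <- matrix(1L, 1, 2, dimnames = list("w1", c("A", "Z")))
  expect_error(pdi_nti_report(tr, comm, reps = 10), "not aligned")
  comm2 <- rbind(w1 = c(1L, 1L, 1L), w2 = c(1L, 0L, 0L))
  colnames(comm2) <- c("A", "B", "C")
  expect_error(pdi_nti_report(tr, comm2, reps = 10, pool = c("A", "B")),
               "pool smaller")
})

test_that("frequency-weighted pools favour common species", {
  tr <- tree4()
  comm <- rbind(w1 = c(1L, 1L, 0L, 0L), w2 = c(1L, 1L, 0L, 1L), w3 = c(1L, 1L, 1L, 0L))
  colnames(comm) <- tr$tip.label
  rw <- pdi_nti_report(tr, comm, reps = 99, seed = 1, weighted = TRUE)
  ru <- pdi_nti_report(tr, comm, reps = 99, seed = 1, weighted = FALSE)
  expect_false(identical(rw$pdi, ru$pdi))
})
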