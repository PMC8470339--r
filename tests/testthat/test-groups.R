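make_attrs <- function(species, lf, dominant = FALSE, invasive = FALSE) {
  data.frame(species = species,
             life_form = factor(lf, levels = c("annual", "perennial", "woody", "other")),
             dominant = rep_len(dominant, length(species)),
             invasive = rep_len(invasive, length(species)),
             stringsAsFactors = FALSE)
}

test_that("life-form proportions are exact on constructed sites and rows sum to 1", {
  tr <- tree4()
  comm <- rbind(mix = c(1L, 1L, 1L, 1L), peren = c(0L, 0L, 1L, 1L))
  colnames(comm) <- tr$tip.label
  attrs <- make_attrs(tr$tip.label, c("annual", "annual", "perennial", "perennial"))
  lf <- lifeform_proportions(comm, attrs)
  expect_equal(lf$site$annual, c(0.5, 0))
  expect_equal(lf$site$perennial, c(0.5, 1))
  expect_equal(rowSums(lf$site[, c("annual", "perennial", "woody", "other")]),
               c(1, 1), ignore_attr = TRUE)
  bad <- make_attrs(c("A", "B", "C"), c("annual", "annual", "woody"))
  expect_error(lifeform_proportions(comm, bad), "without attributes: D")
})

test_that("per-type ranges cover each type's sites", {
  tr <- tree4()
  comm <- rbind(w1 = c(1L, 1L, 0L, 0L), w2 = c(1L, 0L, 1L, 0L), w3 = c(0L, 0L, 1L, 1L))
  colnames(comm) <- tr$tip.label
  attrs <- make_attrs(tr$tip.label, c("annual", "perennial", "perennial", "woody"))
  meta <- data.frame(site = c("w1", "w2", "w3"),
                     wetland_type = factor(c("lake", "lake", "marsh"),
                                           levels = c("lake", "marsh", "coastal", "river", "human-made")))
  lf <- lifeform_proportions(comm, attrs, meta)
  lake <- lf$type_ranges[lf$type_ranges$wetland_type == "lake", ]
  expect_equal(lake$n_sites, 2)
  expect_equal(lake$annual_min, 0.5)   # both lake sites have one annual of two
  expect_equal(lake$perennial_max, 0.5)
  marsh <- lf$type_ranges[lf$type_ranges$wetland_type == "marsh", ]
  expect_equal(marsh$perennial_min, 0.5)
  expect_equal(marsh$woody_max, 0.5)
})

test_that("generator life-form mix is recovered within binomial error", {
  cfg <- synth_config(n_tips = 1000, n_sites = 1, richness_range = c(5, 5),
                      lifeform_mix = c(annual = 0.30, perennial = 0.65,
                                       woody = 0.05, other = 0),
                      seed = 99)
  tr <- generate_tree(cfg)
  attrs <- generate_attributes(tr, cfg)
  shares <- table(factor(attrs$life_form, levels = levels(attrs$life_form))) / 1000
  for (lv in c("annual", "perennial", "woody")) {
    p <- c(annual = 0.30, perennial = 0.65, woody = 0.05)[[lv]]
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(shares[[lv]] - p), 3 * se)
  }
  expect_equal(shares[["other"]], 0)
})

test_that("group_nti is positive for a clade and degenerate for group = pool", {
  set.seed(42)
  tr <- ape::rcoal(40)
  tr$tip.label <- sprintf("sp%02d", 1:40)
  pool <- tr$tip.label
  # a clade of closest relatives: take the subtree under one internal node
  cache_sizes <- ape::prop.part(tr)
  clade <- pool[cache_sizes[[which(lengths(cache_sizes) %in% 5:10)[2]]]]
  gn <- group_nti(tr, clade, pool, reps = 199, seed = 7)
  expect_gt(gn$nti, 0)
  deg <- group_nti(tr, pool, pool, reps = 25, seed = 7)
  expect_true(is.na(deg$nti))
  expect_match(deg$note, "sd is 0")
  expect_error(group_nti(tr, pool[1], pool, reps = 25), "at least 2")
  expect_error(group_nti(tr, c(pool[1], "nope"), pool, reps = 25), "outside the pool")
})

test_that("uniformly drawn groups have NTI centred on 0", {
  set.seed(3)
  tr <- ape::rcoal(60)
  tr$tip.label <- sprintf("sp%02d", 1:60)
  pool <- tr$tip.label
  ntis <- vapply(1:60, function(i) {
    g <- sample(pool, 12)
    group_nti(tr, g, pool, reps = 199, seed = 1000 + i)$nti
  }, numeric(1))
  expect_lt(abs(mean(ntis)), 0.15)
})

test_that("group_separation matches mntd_between and calibrates via permutation", {
  d <- cophenetic_matrix(tree4())
  sep <- group_separation(d, c("A", "B"), c("C", "D"), perm = 199, seed = 2)
  expect_equal(sep$mntd_between_obs, 4)
  expect_true(sep$perm_quantile > 0.5)  # the true split is the most separated one
  same <- group_separation(d, c("A", "B"), c("A", "B"), perm = 0)
  expect_equal(same$mntd_between_obs, 0)
})

test_that("a clade-concentrated flag separates more than random species pairs", {
  cfg <- synth_config(n_tips = 80, n_sites = 2, richness_range = c(5, 10),
                      flag_mode = "clade", invasive_rate = 0.1, seed = 55)
  tr <- generate_tree(cfg)
  attrs <- generate_attributes(tr, cfg)
  inv <- attrs$species[attrs$invasive]
  expect_gte(length(inv), 2)
  d <- cophenetic_matrix(tr)
  sep <- group_separation(d, inv, setdiff(attrs$species, inv), perm = 199, seed = 1)
  # a deep clade sits farther from the rest than shuffled labels do
  expect_gt(sep$mntd_between_obs, sep$perm_mean)
  gn <- group_nti(tr, inv, attrs$species, reps = 199, seed = 1)
  expect_gt(gn$nti, 0)
  none <- synth_config(n_tips = 30, n_sites = 2, richness_range = c(3, 5),
                       dominant_rate = 0, invasive_rate = 0, seed = 5)
  a0 <- generate_attributes(generate_tree(none), none)
  expect_false(any(a0$dominant) || any(a0$invasive))
})
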