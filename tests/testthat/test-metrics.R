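test_that("faith_pd matches hand-enumerated values on the reference tree", {
  tr <- tree4()
  expect_equal(faith_pd(tr, c("A", "B", "C", "D")), 6)    # whole tree
  expect_equal(faith_pd(tr, c("A", "B")), 3)              # A + B + stem
  expect_equal(faith_pd(tr, c("A", "B"), include_root = FALSE), 2)
  expect_equal(faith_pd(tr, "A", include_root = FALSE), 0)
  expect_equal(faith_pd(tr, "A"), 2)                      # root-to-tip path
  expect_error(faith_pd(tr, "Z"), "not found")
})

test_that("within-assemblage MPD and MNTD match hand enumeration", {
  d <- cophenetic_matrix(tree4())
  expect_equal(mpd_within(d, c("A", "B", "C")), 10 / 3)
  expect_equal(mntd_within(d, c("A", "B", "C")), 8 / 3)
  expect_equal(mpd_within(d, c("A", "C")), mntd_within(d, c("A", "C")))
  ds <- cophenetic_matrix(parse_newick("(A:1,B:1,C:1);"))
  expect_equal(mpd_within(ds, c("A", "B", "C")), 2)
  expect_error(mpd_within(d, "A"), "fewer than 2")
  expect_error(mntd_within(d, "A"), "fewer than 2")
})

test_that("between-community MPD and MNTD match hand enumeration and are symmetric", {
  d <- cophenetic_matrix(tree4())
  expect_equal(mpd_between(d, c("A", "B"), c("C", "D")), 4)
  expect_equal(mntd_between(d, c("A", "B"), c("C", "D")), 4)
  expect_equal(mpd_between(d, c("A", "B"), c("A", "B")), 1)  # ordered pairs incl. self
  expect_equal(mntd_between(d, c("A", "B"), c("A", "B")), 0)
  expect_equal(mntd_between(d, "A", c("B", "C")), 8 / 3)
  expect_equal(mpd_between(d, "A", "D"), unname(d["A", "D"]))
  expect_error(mpd_between(d, character(0), "A"), "non-empty")
})

test_that("exclude_shared drops the intersection before averaging", {
  d <- cophenetic_matrix(tree4())
  expect_equal(mpd_between(d, c("A", "C"), c("A", "D"), exclude_shared = TRUE),
               unname(d["C", "D"]))
  expect_error(mpd_between(d, "A", "A", exclude_shared = TRUE), "empty")
})

test_that("all four distance metrics agree with brute-force oracles on random trees", {
  set.seed(77)
  for (rep in 1:20) {
    tr <- random_tree(sample(6:10, 1))
    d <- cophenetic_matrix(tr)
    labs <- tr$tip.label
    for (k in 1:8) {
      s <- sample(labs, sample(2:length(labs), 1))
      expect_equal(mpd_within(d, s), oracle_mpd_within(d, s), tolerance = 1e-12)
      expect_equal(mntd_within(d, s), oracle_mntd_within(d, s), tolerance = 1e-12)
      expect_lte(mntd_within(d, s), mpd_within(d, s) + 1e-12)
      a <- sample(labs, sample(1:4, 1)); b <- sample(labs, sample(1:4, 1))
      expect_equal(mpd_between(d, a, b), oracle_mpd_between(d, a, b), tolerance = 1e-12)
      expect_equal(mntd_between(d, a, b), oracle_mntd_between(d, a, b), tolerance = 1e-12)
      expect_equal(mpd_between(d, a, b), mpd_between(d, b, a), tolerance = 1e-12)
      expect_equal(mntd_between(d, a, b), mntd_between(d, b, a), tolerance = 1e-12)
      expect_equal(faith_pd(tr, s), oracle_pd(tr, s), tolerance = 1e-12)
      expect_equal(faith_pd(tr, s, include_root = FALSE),
                   oracle_pd(tr, s, include_root = FALSE), tolerance = 1e-12)
    }
  }
})

test_that("faith_pd is monotone under species addition and exhausts the tree", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- random_tree(10)
    labs <- sample(tr$tip.label)
    pds <- vapply(seq_along(labs),
                  function(k) faith_pd(tr, labs[seq_len(k)]), numeric(1))
    expect_true(all(diff(pds) >= -1e-12))
    expect_equal(pds[length(labs)], total_branch_length(tr), tolerance = 1e-12)
  }
})
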