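test_that("category profiles follow the assignment-counting rules", {
  lib <- gene_set_library(list(catA = c("g1"), catB = c("g2")),
                          universe = c("g1", "g2", "g3"))
  prof <- category_profile(lib, c("g1", "g2"))
  expect_equal(unname(prof$proportions), c(0.5, 0.5))
  expect_equal(sum(prof$proportions), 1)

  # one gene in two categories contributes one assignment to each
  lib2 <- gene_set_library(list(catA = c("g1"), catB = c("g1")),
                           universe = c("g1", "g2"))
  prof2 <- category_profile(lib2, "g1")
  expect_equal(unname(prof2$proportions), c(0.5, 0.5))
  # per-gene normalization divides by classified genes instead
  prof2g <- category_profile(lib2, "g1", per_gene = TRUE)
  expect_equal(unname(prof2g$proportions), c(1, 1))

  # unclassified genes are tallied but excluded from proportions
  prof3 <- category_profile(lib, c("g1", "g3"))
  expect_equal(prof3$unclassified, 1L)
  expect_equal(sum(prof3$proportions), 1)
})

test_that("profile distances are Euclidean with the stated hand values", {
  mk <- function(g, p) structure(list(group = g, categories = c("c1", "c2"),
                                      proportions = p, counts = p,
                                      unclassified = 0L),
                                 class = "category_profile")
  expect_equal(profile_distances(list(mk("A", c(1, 0)), mk("B", c(1, 0))))["A", "B"], 0)
  expect_equal(profile_distances(list(mk("A", c(1, 0)), mk("B", c(0, 1))))["A", "B"],
               sqrt(2), tolerance = 1e-12)
  expect_equal(profile_distances(list(mk("A", c(0.5, 0.5)),
                                      mk("B", c(0.3, 0.7))))["A", "B"],
               sqrt(0.08), tolerance = 1e-12)

  bad <- structure(list(group = "C", categories = c("x1", "x2"),
                        proportions = c(1, 0), counts = c(1, 0),
                        unclassified = 0L), class = "category_profile")
  expect_error(profile_distances(list(mk("A", c(1, 0)), bad)), "mismatched")

  # triangle inequality on random profiles
  set.seed(5)
  profs <- lapply(1:4, function(i) {
    p <- runif(6); mk(paste0("P", i), p / sum(p))
  })
  profs <- lapply(profs, function(p) { p$categories <- paste0("c", 1:6); p })
  d <- profile_distances(profs)
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("a planted first-level skew yields a majority category for that group", {
  b <- default_bundle()
  net <- bundle_network(b, cap = "unlimited")
  coll <- collect_targets(net)
  fl <- read_gmt(b$paths[["first_level"]])
  skew <- b$manifest$category_skew$TY
  prof <- category_profile(fl, coll$sets$TY, group = "TY")
  expect_equal(names(which.max(prof$proportions)), skew$category)
  # per-gene view: more than half of TY genes fall in the skewed category
  prof_g <- category_profile(fl, coll$sets$TY, group = "TY", per_gene = TRUE)
  expect_gt(prof_g$proportions[[skew$category]], 0.5)

  profs <- lapply(coll$groups, function(g) category_profile(fl, coll$sets[[g]], group = g))
  d <- profile_distances(profs)
  # the skewed TY profile sits farther from the rest than any non-TY pair
  non_ty <- d[c("SE", "SY", "TE"), c("SE", "SY", "TE")]
  expect_gt(min(d["TY", c("SE", "SY", "TE")]), max(non_ty))
})
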