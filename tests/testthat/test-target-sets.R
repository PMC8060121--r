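test_that("collect_targets unions genes over each group's compounds", {
  net <- tiny_network(c(H1 = "A", H2 = "B"),
                      list(H1 = "c1", H2 = "c2"),
                      ct_df(c("c1", "c1", "c2"), c("g1", "g2", "g2"), 900),
                      groups = c("A", "B"))
  coll <- collect_targets(net)
  expect_equal(coll$sets$A, c("G1", "G2"))  # symbols are upper-cased on load
  expect_equal(coll$sets$B, "G2")
  expect_equal(unname(coll$herb_counts[c("A", "B")]), c(1L, 1L))

  # no surviving edges -> all sets empty (and empty groups warn)
  net2 <- tiny_network(c(H1 = "A", H2 = "B"), list(H1 = "c1", H2 = "c2"),
                       ct_df(c("c1", "c2"), c("g1", "g2"), 100),
                       score_threshold = 700, groups = c("A", "B", "C"))
  expect_warning(coll2 <- collect_targets(net2), "no herbs")
  expect_true(all(lengths(coll2$sets) == 0L))
})

test_that("planted generator pools are recovered exactly from the network", {
  b <- default_bundle()
  net <- bundle_network(b, cap = "unlimited")
  coll <- collect_targets(net)
  expect_identical(coll$sets, b$manifest$pools)
})

test_that("overlap table matches hand examples and its own invariants", {
  ov <- overlap_table(sets_collection(list(A = c("1", "2"), B = c("2", "3"))))
  expect_equal(ov$pairwise["A", "B"], 1L)
  expect_equal(unname(ov$exclusive), c(1L, 1L))
  expect_equal(ov$union_size, 3L)

  ov2 <- overlap_table(sets_collection(list(A = c("x", "y"), B = c("x", "y"))))
  expect_equal(ov2$pairwise["A", "B"], 2L)
  expect_equal(unname(ov2$exclusive), c(0L, 0L))
})

test_that("Venn region counts equal a per-gene membership tally on random sets", {
  universe <- sprintf("g%02d", 1:50)
  for (seed in 1:10) {
    set.seed(seed)
    sets <- lapply(setNames(1:4, c("A", "B", "C", "D")), function(i) {
      sample(universe, sample(5:20, 1))
    })
    ov <- overlap_table(sets_collection(sets))

    # oracle: tally each gene's membership pattern directly
    union_genes <- unique(unlist(sets))
    patterns <- vapply(union_genes, function(g) {
      paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
            collapse = "+")
    }, "")
    oracle <- table(patterns)
    got <- setNames(ov$regions$count, ov$regions$pattern)
    for (pat in names(oracle)) {
      expect_equal(unname(got[[pat]]), unname(as.integer(oracle[[pat]])),
                   info = sprintf("seed %d pattern %s", seed, pat))
    }
    # invariants: regions sum to the union; pairwise >= full intersection
    expect_equal(sum(ov$regions$count), length(union_genes))
    four_way <- length(Reduce(intersect, sets))
    expect_true(all(ov$pairwise[upper.tri(ov$pairwise)] >= four_way))
  }
})

test_that("exclusive proportion follows its declared conventions", {
  coll <- sets_collection(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(exclusive_proportion(coll, "A"), 0.5)

  disj <- sets_collection(list(A = c("a1", "a2"), B = c("b1")))
  expect_equal(exclusive_proportion(disj, "A"), 1)
  expect_equal(exclusive_proportion(disj, "B"), 1)

  nested <- sets_collection(list(A = c("g1"), B = c("g1", "g2")))
  expect_equal(exclusive_proportion(nested, "A"), 0)

  empty <- sets_collection(list(A = character(0), B = c("g1")))
  expect_equal(exclusive_proportion(empty, "A"), 0)  # 0/0 convention

  expect_error(exclusive_proportion(coll, "Z"), "unknown group")
})
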