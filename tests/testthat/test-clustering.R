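test_that("cosine distance matches hand arithmetic and rejects zero vectors", {
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero vector")
  expect_error(cosine_distance(c(1, 2), c(1, 2, 3)), "equal length")

  # invariance to positive rescaling of either argument
  set.seed(4)
  for (i in 1:10) {
    u <- runif(6); v <- runif(6)
    expect_equal(cosine_distance(u, v), cosine_distance(3.7 * u, v),
                 tolerance = 1e-12)
    expect_equal(cosine_distance(u, v), cosine_distance(u, 0.01 * v),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA reproduces the hand-worked merge sequence and newick", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  den <- upgma(d)
  expect_equal(den$heights, c(1, 3))
  expect_equal(den$merges[[1]]$members, c("A", "B"))
  expect_equal(den$newick, "((A:1,B:1):2,C:3);")

  # equal distances: first merge is the lexicographically smallest pair
  d2 <- matrix(5, 3, 3, dimnames = list(c("C", "A", "B"), c("C", "A", "B")))
  diag(d2) <- 0
  expect_equal(upgma(d2)$merges[[1]]$members, c("A", "B"))

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2,
                            dimnames = list(c("A", "B"), c("A", "B")))),
               "symmetric")
})

test_that("UPGMA agrees with average-linkage hclust on random matrices", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 5
    labs <- LETTERS[1:n]
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 1, 10)  # continuous: no ties
    d <- d + t(d)
    den <- upgma(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    # cophenetic distances (= merge distance of the joining cluster) agree
    expect_equal(cophenetic_matrix(den)[labs, labs],
                 as.matrix(stats::cophenetic(hc))[labs, labs],
                 tolerance = 1e-9, info = paste("seed", seed))
    # newick parses and its patristic distances are the half-height tree
    tr <- ape::read.tree(text = den$newick)
    pat <- ape::cophenetic.phylo(tr)[labs, labs]
    expect_equal(pat, cophenetic_matrix(den)[labs, labs], tolerance = 1e-6)
  }
})

test_that("UPGMA trees are ultrametric (three-point condition)", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 6
    labs <- letters[1:n]
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 1, 10)
    d <- d + t(d)
    cm <- cophenetic_matrix(upgma(d))
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(cm[i, j], max(cm[i, k], cm[j, k]) + 1e-9)
    }
  }
})

test_that("incidence matrix counts compound support per gene and group", {
  net <- tiny_network(c(H1 = "A", H2 = "B"),
                      list(H1 = c("c1", "c2"), H2 = "c3"),
                      ct_df(c("c1", "c2", "c3"), c("G1", "G1", "G1"), 900))
  inc <- incidence_matrix(net)
  expect_equal(inc["G1", "A"], 2)    # two distinct compound-target edges
  expect_equal(inc["G1", "B"], 1)
  bin <- incidence_matrix(net, binary = TRUE)
  expect_true(all(bin %in% c(0, 1)))
  expect_equal(bin["G1", "A"], 1)
})

test_that("planted overlap structure clusters SE with SY first and TY last at every cap", {
  b <- default_bundle()
  net <- bundle_network(b, cap = "unlimited")
  cl <- cluster_groups(net, caps = list(10, 50, 100, 500, "unlimited"))
  expect_true(cl$same_topology)
  for (nm in names(cl$dendrograms)) {
    den <- cl$dendrograms[[nm]]
    expect_equal(den$merges[[1]]$members, c("SE", "SY"), info = paste("cap", nm))
    last <- den$merges[[length(den$merges)]]
    expect_true(any(vapply(last$children, identical, logical(1), y = "TY")),
                info = paste("cap", nm))
  }

  # listing a cap twice yields identical trees; two groups are trivially robust
  cl2 <- cluster_groups(net, caps = list(10, 10))
  expect_identical(cl2$dendrograms[[1]], cl2$dendrograms[[2]])
  expect_true(cl2$same_topology)
})

test_that("groups with no surviving targets are reported by name", {
  net <- tiny_network(c(H1 = "A", H2 = "B"), list(H1 = "c1", H2 = "c2"),
                      ct_df(c("c1", "c2"), c("G1", "G2"), c(900, 100)),
                      score_threshold = 700, groups = c("A", "B"))
  expect_error(group_distances(net), "B")
})
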