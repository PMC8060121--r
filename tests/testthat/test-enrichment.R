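test_that("expected counts reproduce the published two-decimal table values", {
  # within one published table all rows share n_mapped/N, so any row's ratio
  # calibrates the rest; anchor on the largest reference count per table
  path <- system.file("extdata", "go_overrep_tables.tsv", package = "scnetpharm")
  tab <- utils::read.delim(path, comment.char = "#")
  for (g in unique(tab$group)) {
    rows <- tab[tab$group == g, ]
    a <- which.max(rows$ref_count)
    pred <- expected_count(rows$expected[a], rows$ref_count, rows$ref_count[a])
    tol <- 0.005 * (1 + rows$ref_count / rows$ref_count[a]) + 1e-9
    expect_true(all(abs(pred - rows$expected) <= tol), info = g)
  }
  expect_equal(expected_count(50, 0, 1000), 0)
  expect_error(expected_count(10, 5, 0), "positive")
})

test_that("one-sided Fisher p equals direct enumeration", {
  expect_equal(fisher_overrep(4, 5, 8, 20), 7280 / 125970, tolerance = 1e-12)
  expect_equal(fisher_overrep(0, 5, 8, 20), 1)
  expect_error(fisher_overrep(6, 5, 8, 20), "inconsistent")

  set.seed(8)
  for (i in 1:25) {
    N <- sample(5:40, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(fisher_overrep(k, K, n, N), enum_hyper_tail(k, K, n, N),
                 tolerance = 1e-12,
                 info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }

  # p is non-increasing in k at fixed margins
  ks <- 0:5
  ps <- fisher_overrep(ks, 5, 8, 20)
  expect_true(all(diff(ps) <= 0))

  # binomial alternative uses the K/N success probability
  expect_equal(fisher_overrep(3, 10, 6, 100, method = "binomial"),
               stats::pbinom(2, 6, 0.1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.07), 0.07)
  p <- c(0.04, 0.001, 0.9, 0.02)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))                     # adjusted never below raw
  expect_equal(order(adj), order(p))             # order preserved
})

test_that("combined score vanishes when p = 1 or the rank deviation is zero", {
  lib <- gene_set_library(list(t1 = c("a", "b", "c"), t2 = c("d", "e", "f"),
                               t3 = c("a", "d", "g")),
                          universe = letters[1:10])
  p_obs <- c(t1 = 1, t2 = 0.5, t3 = 0.2)
  zc <- rank_z_and_combined(lib, c("a", "b"), p_obs, R_cal = 50, seed = 2)
  expect_equal(zc$combined[zc$term_id == "t1"], 0)  # ln(1) = 0
  # z = 0 forces combined = 0 regardless of p
  expect_true(all(zc$combined[zc$z == 0] == 0))
})

test_that("a target list equal to one isolated term ranks that term first", {
  lib <- gene_set_library(list(hit = sprintf("h%d", 1:8),
                               bg1 = sprintf("b%d", 1:10),
                               bg2 = sprintf("b%d", 6:15)),
                          universe = c(sprintf("h%d", 1:8), sprintf("b%d", 1:15),
                                       sprintf("x%d", 1:30)))
  res <- overrepresentation(lib, sprintf("h%d", 1:8), R_cal = 100, seed = 3)
  expect_equal(res$term_id[1], "hit")
  expect_true(res$significant[1])
  expect_equal(attr(res, "n_mapped"), 8L)
  expect_true(all(res$p_adj >= res$p))

  # expected counts over disjoint exhaustive terms sum to n_mapped
  part <- gene_set_library(list(p1 = letters[1:5], p2 = letters[6:15],
                                p3 = letters[16:26]))
  res2 <- overrepresentation(part, letters[c(1:3, 7, 20)], R_cal = 50, seed = 1)
  expect_equal(sum(res2$expected), attr(res2, "n_mapped"))

  expect_error(overrepresentation(lib, c("zz1", "zz2")), "unmapped")
})

test_that("the planted enriched term attains the top combined score", {
  b <- default_bundle()
  net <- bundle_network(b, cap = "unlimited")
  coll <- collect_targets(net)
  lib <- read_gmt(b$paths[["go_slim"]])
  pg <- b$manifest$planted_term$group
  res <- overrepresentation(lib, coll$sets[[pg]], R_cal = 200, seed = 21)
  expect_equal(res$term_id[1], b$manifest$planted_term$id)
  expect_true(res$significant[1])
})
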