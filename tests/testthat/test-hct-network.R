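test_that("herb catalog loader validates structure and handles edge cases", {
  # header-only file -> zero records
  empty <- load_herb_catalog(write_tmp_tsv("herb_id\tgroup\tlocal_name\tlatin_name"))
  expect_s3_class(empty, "herb_catalog")
  expect_equal(nrow(empty), 0L)

  # duplicated herb_id is rejected
  dup <- c("herb_id\tgroup\tlocal_name\tlatin_name",
           "H1\tSE\tx\ty", "H1\tSY\tx\ty")
  expect_error(load_herb_catalog(write_tmp_tsv(dup)), "duplicate herb_id")

  # group label outside the configured set is rejected
  bad <- c("herb_id\tgroup\tlocal_name\tlatin_name", "H1\tXX\tx\ty")
  expect_error(load_herb_catalog(write_tmp_tsv(bad)), "unknown group")
})

test_that("score threshold is strict and the cap keeps top scores with lexicographic ties", {
  # compound with 3 targets under a cap of 10: all retained
  net <- tiny_network(c(H1 = "A"), list(H1 = "c1"),
                      ct_df("c1", c("G1", "G2", "G3"), c(900, 800, 750)),
                      score_threshold = 700, cap = 10)
  expect_equal(sort(net$compound_target$target_gene), c("G1", "G2", "G3"))

  # 12 equal-score targets, cap 10: the 10 lexicographically smallest survive
  genes <- sprintf("G%02d", 12:1)  # deliberately unsorted input
  net2 <- tiny_network(c(H1 = "A"), list(H1 = "c1"),
                       ct_df("c1", genes, 900), score_threshold = 700, cap = 10)
  expect_equal(net2$compound_target$target_gene, sprintf("G%02d", 1:10))

  # score exactly at the threshold is dropped (strict >)
  net3 <- tiny_network(c(H1 = "A"), list(H1 = "c1"),
                       ct_df("c1", c("G1", "G2"), c(700, 701)),
                       score_threshold = 700, cap = 10)
  expect_equal(net3$compound_target$target_gene, "G2")
  expect_equal(net3$orphaned, character(0))

  # orphaned compounds remain as flagged nodes
  net4 <- tiny_network(c(H1 = "A"), list(H1 = c("c1", "c2")),
                       ct_df(c("c1", "c2"), c("G1", "G2"), c(900, 100)),
                       score_threshold = 700, cap = 10)
  expect_equal(net4$orphaned, "c2")
  expect_true("c2" %in% net4$compounds)
})

test_that("malformed edge tables raise validation errors", {
  herbs <- tmp_catalog(c(H1 = "A"))
  hc_bad <- data.frame(herb_id = "H9", compound_id = "c1")
  ct <- ct_df("c1", "G1", 900)
  expect_error(build_network(herbs, hc_bad, ct), "unknown herb")

  hc <- data.frame(herb_id = "H1", compound_id = "c1")
  ct_bad <- data.frame(compound_id = "c1", target_gene = "G1", score = "high")
  expect_error(build_network(herbs, hc, ct_bad), "malformed")

  ct_dup <- ct_df(c("c1", "c1"), c("G1", "G1"), c(900, 800))
  expect_error(build_network(herbs, hc, ct_dup), "duplicate")
})

test_that("capping is idempotent, monotone in cap, and threshold filtering is monotone", {
  b <- default_bundle()
  net <- bundle_network(b, cap = "unlimited")

  per_compound <- function(n) table(factor(n$compound_target$compound_id,
                                           levels = n$compounds))
  edge_keys <- function(n) paste(n$compound_target$compound_id,
                                 n$compound_target$target_gene)

  caps <- c(3, 10, 50)
  prev_keys <- character(0)
  for (cap in caps) {
    capped <- apply_cap(net, cap)
    twice <- apply_cap(capped, cap)
    expect_identical(capped$compound_target, twice$compound_target)
    expect_true(all(per_compound(capped) <= cap))
    # monotone: smaller cap's edges are a subset of larger cap's
    expect_true(all(prev_keys %in% edge_keys(capped)))
    prev_keys <- edge_keys(capped)
  }
  expect_true(all(prev_keys %in% edge_keys(net)))

  # raising the score threshold never adds edges
  herbs <- load_herb_catalog(b$paths[["herb_catalog"]])
  lo <- build_network(herbs, b$paths[["herb_compound"]],
                      b$paths[["compound_target"]], score_threshold = 600,
                      cap = "unlimited")
  expect_true(all(edge_keys(net) %in% edge_keys(lo)))
  expect_gte(nrow(lo$compound_target), nrow(net$compound_target))
})

test_that("network JSON round-trips exactly", {
  b <- default_bundle()
  net <- bundle_network(b, cap = 10)
  path <- tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$compound_target, net$compound_target)
  expect_equal(back$herb_compound, net$herb_compound)
  expect_equal(back$orphaned, net$orphaned)
  expect_equal(back$cap, net$cap)
  expect_equal(collect_targets(back)$sets, collect_targets(net)$sets)
})
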