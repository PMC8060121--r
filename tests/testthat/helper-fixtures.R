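# In-code fixture builders shared across the test files. Everything is
# written to tempfiles at test time; no binary fixtures exist.

write_tmp_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# A minimal herb catalog with the given herb_id -> group assignment.
tmp_catalog <- function(assign, groups = c("A", "B", "C", "D")) {
  lines <- c("herb_id\tgroup\tlocal_name\tlatin_name",
             vapply(names(assign), function(h) {
               sprintf("%s\t%s\tlocal %s\tlatin %s", h, assign[[h]], h, h)
             }, ""))
  load_herb_catalog(write_tmp_tsv(lines), groups = groups)
}

# Build an hct_network directly from explicit edge tables.
# hc: list herb_id -> compound ids; ct: data.frame(compound_id, target_gene,
# score).
tiny_network <- function(assign, hc, ct, groups = c("A", "B", "C", "D"),
                         score_threshold = 0, cap = "unlimited") {
  herbs <- tmp_catalog(assign, groups = groups)
  hc_df <- do.call(rbind, lapply(names(hc), function(h) {
    data.frame(herb_id = h, compound_id = hc[[h]], stringsAsFactors = FALSE)
  }))
  build_network(herbs, hc_df, ct, score_threshold = score_threshold, cap = cap)
}

ct_df <- function(compound_id, target_gene, score = 900) {
  data.frame(compound_id = compound_id, target_gene = target_gene,
             score = score, stringsAsFactors = FALSE)
}

# Target-set collection built directly from named gene lists (bypasses the
# network) for overlap / exclusivity unit tests.
sets_collection <- function(sets) {
  structure(list(groups = names(sets), sets = lapply(sets, sort),
                 herb_counts = setNames(rep(1L, length(sets)), names(sets))),
            class = "target_sets")
}

# Small planted bundle used by several files; cached per session.
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_bundle(synthetic_config(), seed = 101,
                                out_dir = file.path(tempdir(), "scnp_default"))
    }
    cache
  }
})

bundle_network <- function(bundle, cap = "unlimited", score_threshold = 700) {
  herbs <- load_herb_catalog(bundle$paths[["herb_catalog"]])
  build_network(herbs, bundle$paths[["herb_compound"]],
                bundle$paths[["compound_target"]],
                score_threshold = score_threshold, cap = cap)
}

# Brute-force one-sided hypergeometric tail by direct binomial-coefficient
# enumeration (independent of phyper/dhyper).
enum_hyper_tail <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Small cached null-structure bundle factory for calibration tests.
null_config <- function() {
  synthetic_config(structure = "null", universe_size = 300,
                   pool_sizes = c(SE = 60, SY = 60, TE = 60, TY = 60),
                   compounds_per_herb = 6, diseases_per_chapter = 1,
                   terms_per_category = 1)
}
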