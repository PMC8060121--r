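#' Shuffle compound-target interactions
#'
#' Null model for the exclusivity test: the target endpoints of the
#' compound-target edges (together with their scores, which belong to the
#' interaction) are permuted uniformly at random across edges. Before
#' collapsing, every compound keeps its edge count and the global multiset
#' of target endpoints is conserved; duplicate (compound, target) pairs
#' created by the shuffle are then collapsed, keeping the highest score.
#' The shuffle acts on the already filtered and capped network.
#'
#' @param network an \code{hct_network} with at least one compound-target
#'   edge.
#' @return a new \code{hct_network} with shuffled edges.
#' @export
shuffle_edges <- function(network) {
  assert_that(inherits(network, "hct_network"), "`network` must be an hct_network")
  ct <- network$compound_target
  if (nrow(ct) >= 2L) {
    perm <- sample.int(nrow(ct))
    ct$target_gene <- ct$target_gene[perm]
    ct$score <- ct$score[perm]
    # collapse duplicates, keep highest score
    ct <- ct[order(ct$compound_id, ct$target_gene, -ct$score), , drop = FALSE]
    dup <- duplicated(ct[, c("compound_id", "target_gene")])
    ct <- ct[!dup, , drop = FALSE]
    rownames(ct) <- NULL
  }
  network$compound_target <- ct
  network$orphaned <- setdiff(network$compounds, unique(ct$compound_id))
  network
}

#' Permutation test for target-set exclusivity
#'
#' Tests, per constitution type, whether the proportion of target genes
#' exclusive to that type exceeds what random reassignment of compound-target
#' interactions would produce. The observed statistic is
#' \code{\link{exclusive_proportion}} on the unshuffled network; the null
#' distribution comes from \code{R} independent shuffles
#' (\code{\link{shuffle_edges}}), each re-collected into per-type sets and
#' re-scored. One-sided (greater) empirical p-values use the add-one rule
#' \eqn{p = (1 + \#\{null \ge obs\}) / (R + 1)}, so p is never 0. The pooled
#' mean exclusive proportion across types is tested the same way.
#'
#' @param network an \code{hct_network}.
#' @param R number of permutations (default 999).
#' @param seed integer seed; set for reproducibility of the null.
#' @return list of class \code{permutation_result}: \code{observed} and
#'   \code{p_values} (named vectors incl. \code{"pooled"}),
#'   \code{null_samples} (R x groups matrix, plus pooled column), \code{R},
#'   \code{seed}.
#' @export
permutation_test <- function(network, R = 999, seed = NULL) {
  assert_that(inherits(network, "hct_network"), "`network` must be an hct_network")
  assert_that(is.numeric(R) && length(R) == 1L && R >= 1 && R == floor(R),
              "R must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  groups <- network$groups

  # Vectorized statistic: per edge, which groups its compound belongs to.
  # Set unions ignore scores and duplicate collapse, so permuting the gene
  # column is equivalent to shuffle_edges() + collect_targets().
  ct <- network$compound_target
  assert_that(nrow(ct) >= 2L, "network needs at least two compound-target edges")
  hc <- network$herb_compound
  herb_group <- setNames(network$herbs$group, network$herbs$herb_id)
  comp_groups <- vapply(groups, function(g) {
    comps_g <- unique(hc$compound_id[herb_group[hc$herb_id] == g])
    ct$compound_id %in% comps_g
  }, logical(nrow(ct)))          # n_edges x n_groups membership
  gene_idx <- factor(ct$target_gene)

  prop_from_assignment <- function(idx) {
    memb <- rowsum(comp_groups + 0, idx) > 0   # genes x groups
    sizes <- colSums(memb)
    excl <- colSums(memb & rowSums(memb) == 1L)
    ifelse(sizes > 0, excl / sizes, 0)
  }
  observed <- prop_from_assignment(gene_idx)
  observed <- c(observed, pooled = mean(observed))

  null_samples <- matrix(NA_real_, nrow = R, ncol = length(groups) + 1L,
                         dimnames = list(NULL, c(groups, "pooled")))
  for (r in seq_len(R)) {
    null_prop <- prop_from_assignment(gene_idx[sample.int(length(gene_idx))])
    null_samples[r, ] <- c(null_prop, mean(null_prop))
  }
  p_values <- vapply(colnames(null_samples), function(g) {
    (1 + sum(null_samples[, g] >= observed[[g]])) / (R + 1)
  }, numeric(1))

  structure(list(observed = observed, null_samples = null_samples,
                 p_values = p_values, R = R, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Exclusivity permutation test (R = %d)\n", x$R))
  for (g in names(x$observed)) {
    cat(sprintf("  %-7s observed %.4f  p = %.4g\n",
                g, x$observed[[g]], x$p_values[[g]]))
  }
  invisible(x)
}
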