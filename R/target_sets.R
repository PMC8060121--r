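#' Collect per-group target gene sets from a network
#'
#' For each constitution type, takes the union of target genes over all
#' surviving compound-target edges of all compounds linked to that type's
#' herbs. A compound shared by herbs of several types contributes its targets
#' to each of them.
#'
#' @param network an \code{hct_network} from \code{\link{build_network}}.
#' @return an object of class \code{target_sets}: list with \code{groups}
#'   (ordered labels), \code{sets} (named list, group -> sorted character
#'   vector of gene symbols) and \code{herb_counts} (named integer vector).
#' @examples
#' \dontrun{
#' ts <- collect_targets(net)
#' lengths(ts$sets)
#' }
#' @export
collect_targets <- function(network) {
  assert_that(inherits(network, "hct_network"), "`network` must be an hct_network")
  groups <- network$groups
  hc <- network$herb_compound
  ct <- network$compound_target
  herb_group <- setNames(network$herbs$group, network$herbs$herb_id)
  sets <- setNames(vector("list", length(groups)), groups)
  herb_counts <- setNames(integer(length(groups)), groups)
  for (g in groups) {
    herbs_g <- network$herbs$herb_id[network$herbs$group == g]
    herb_counts[[g]] <- length(herbs_g)
    if (!length(herbs_g)) {
      warning("group ", g, " has no herbs; its target set is empty")
      sets[[g]] <- character()
      next
    }
    comps <- unique(hc$compound_id[hc$herb_id %in% herbs_g])
    sets[[g]] <- sort(unique(ct$target_gene[ct$compound_id %in% comps]))
  }
  structure(list(groups = groups, sets = sets, herb_counts = herb_counts),
            class = "target_sets")
}

#' @export
print.target_sets <- function(x, ...) {
  cat("Target gene sets per constitution type\n")
  for (g in x$groups) {
    cat(sprintf("  %s: %d genes (%d herbs)\n", g, length(x$sets[[g]]),
                x$herb_counts[[g]]))
  }
  invisible(x)
}

#' Venn-region overlap counts between group target sets
#'
#' Computes the exact count of genes in every non-empty intersection pattern
#' (Venn region) over the group sets by inclusion-exclusion: the count of the
#' region "exactly the groups in S" is
#' \eqn{\sum_{T \supseteq S} (-1)^{|T|-|S|} |\cap_{g \in T} A_g|}.
#' Also reports pairwise shared counts (genes in both sets, regardless of
#' other memberships) and exclusive counts per group.
#'
#' @param collection a \code{target_sets} object with at least two groups.
#' @return list of class \code{overlap_table}: \code{regions} data.frame
#'   (\code{pattern} such as \code{"SE+SY"}, \code{count}), \code{pairwise}
#'   symmetric matrix of shared counts (diagonal = set sizes),
#'   \code{exclusive} named integer vector, and \code{union_size}.
#' @export
overlap_table <- function(collection) {
  assert_that(inherits(collection, "target_sets"), "`collection` must be target_sets")
  groups <- collection$groups
  assert_that(length(groups) >= 2L, "need at least two groups")
  sets <- collection$sets

  n_g <- length(groups)
  subsets <- lapply(seq_len(2^n_g - 1L), function(m) {
    groups[bitwAnd(m, bitwShiftL(1L, seq_len(n_g) - 1L)) > 0L]
  })
  inter_size <- vapply(subsets, function(s) {
    length(Reduce(intersect, sets[s]))
  }, integer(1))
  names(inter_size) <- vapply(subsets, paste, "", collapse = "+")

  region <- vapply(seq_along(subsets), function(i) {
    s <- subsets[[i]]
    tot <- 0
    for (j in seq_along(subsets)) {
      t <- subsets[[j]]
      if (all(s %in% t)) {
        tot <- tot + (-1)^(length(t) - length(s)) * inter_size[[j]]
      }
    }
    as.integer(round(tot))
  }, integer(1))
  regions <- data.frame(pattern = names(inter_size), count = region,
                        stringsAsFactors = FALSE)
  regions <- regions[regions$count > 0L | lengths(subsets) == 1L, , drop = FALSE]
  rownames(regions) <- NULL

  pairwise <- matrix(0L, n_g, n_g, dimnames = list(groups, groups))
  for (a in groups) for (b in groups) {
    pairwise[a, b] <- length(intersect(sets[[a]], sets[[b]]))
  }
  exclusive <- setNames(vapply(groups, function(g) {
    others <- unlist(sets[setdiff(groups, g)], use.names = FALSE)
    sum(!(sets[[g]] %in% others))
  }, integer(1)), groups)

  structure(list(regions = regions, pairwise = pairwise, exclusive = exclusive,
                 union_size = length(unique(unlist(sets, use.names = FALSE)))),
            class = "overlap_table")
}

#' Proportion of a group's targets found in no other group
#'
#' The exclusivity statistic used by the permutation test: the fraction of a
#' group's target genes that belong to no other group's set. Defined as 0
#' for an empty set so the statistic is always available.
#'
#' @param collection a \code{target_sets} object.
#' @param group group label present in the collection.
#' @return number in [0, 1].
#' @export
exclusive_proportion <- function(collection, group) {
  assert_that(inherits(collection, "target_sets"), "`collection` must be target_sets")
  assert_that(group %in% collection$groups, "unknown group: ", group)
  own <- collection$sets[[group]]
  if (!length(own)) return(0)
  others <- unlist(collection$sets[setdiff(collection$groups, group)],
                   use.names = FALSE)
  sum(!(own %in% others)) / length(own)
}
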