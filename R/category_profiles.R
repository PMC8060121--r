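#' First-level category proportion profile of a gene list
#'
#' Assigns each gene to the first-level annotation categories containing it
#' (a gene in several categories contributes one assignment to each) and
#' normalizes assignment counts to proportions. Genes in no category are
#' tallied as \code{unclassified} and excluded from the proportions; set
#' \code{per_gene = TRUE} to divide by the number of classified genes
#' instead of the number of assignments (proportions then need not sum
#' to 1).
#'
#' @param library first-level \code{gene_set_library} (one set per
#'   category).
#' @param genes character vector of gene symbols.
#' @param group label attached to the profile.
#' @param per_gene normalize by classified-gene count instead of assignment
#'   count.
#' @return object of class \code{category_profile}: list with \code{group},
#'   \code{categories}, \code{proportions} (named, ordered like the
#'   library's terms), \code{counts}, \code{unclassified}.
#' @export
category_profile <- function(library, genes, group = "all", per_gene = FALSE) {
  assert_that(inherits(library, "gene_set_library"), "`library` must be a gene_set_library")
  genes <- unique(normalize_gene(genes))
  cats <- names(library$terms)
  counts <- setNames(vapply(library$terms, function(g) sum(genes %in% g),
                            integer(1)), cats)
  classified <- genes[genes %in% unlist(library$terms, use.names = FALSE)]
  unclassified <- length(genes) - length(classified)
  denom <- if (per_gene) length(classified) else sum(counts)
  proportions <- if (denom > 0) counts / denom else counts * 0
  structure(list(group = group, categories = cats,
                 proportions = proportions, counts = counts,
                 unclassified = unclassified),
            class = "category_profile")
}

#' @export
print.category_profile <- function(x, ...) {
  cat(sprintf("Category profile for %s (%d unclassified genes)\n",
              x$group, x$unclassified))
  top <- sort(x$proportions, decreasing = TRUE)
  for (nm in names(head(top, 5))) {
    cat(sprintf("  %-30s %.3f\n", nm, top[[nm]]))
  }
  invisible(x)
}

#' Euclidean distances between category profiles
#'
#' Pairwise Euclidean distance between the proportion vectors of the given
#' profiles; all profiles must share the same ordered category list.
#'
#' @param profiles list of \code{category_profile} objects.
#' @return symmetric distance matrix labelled by the profiles' groups.
#' @export
profile_distances <- function(profiles) {
  assert_that(length(profiles) >= 2L, "need at least two profiles")
  assert_that(all(vapply(profiles, inherits, logical(1), "category_profile")),
              "all elements must be category_profile objects")
  cats <- profiles[[1]]$categories
  for (p in profiles) {
    assert_that(identical(p$categories, cats),
                "profiles have mismatched category lists")
  }
  labels <- vapply(profiles, `[[`, "", "group")
  assert_that(!anyDuplicated(labels), "duplicate group labels among profiles")
  mat <- do.call(rbind, lapply(profiles, `[[`, "proportions"))
  d <- as.matrix(stats::dist(mat, method = "euclidean"))
  dimnames(d) <- list(labels, labels)
  d
}
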