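#' Cosine distance between nonnegative profile vectors
#'
#' \eqn{d(u, v) = 1 - u \cdot v / (\|u\| \|v\|)}. For nonnegative inputs the
#' result lies in [0, 1]. Zero vectors have no direction, so the distance is
#' undefined and an error is raised rather than a value guessed.
#'
#' @param u,v numeric vectors of equal length, nonnegative, each with at
#'   least one nonzero entry.
#' @return number in [0, 1].
#' @export
cosine_distance <- function(u, v) {
  assert_that(length(u) == length(v), "vectors must have equal length")
  assert_that(all(u >= 0) && all(v >= 0), "profiles must be nonnegative")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  assert_that(nu > 0 && nv > 0, "cosine distance undefined for a zero vector")
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 1)  # clamp floating-point residue
}

#' Per-gene, per-group incidence matrix of a network
#'
#' Rows are target genes (the union over groups), columns the constitution
#' types. The weighted entry counts the distinct compound-target edges of
#' that group's compounds supporting the gene (the "how many compounds hit
#' this target" signal); \code{binary = TRUE} reduces entries to presence /
#' absence.
#'
#' @param network an \code{hct_network}.
#' @param binary logical; return 0/1 incidence instead of support counts.
#' @return numeric matrix, genes x groups.
#' @export
incidence_matrix <- function(network, binary = FALSE) {
  assert_that(inherits(network, "hct_network"), "`network` must be an hct_network")
  groups <- network$groups
  ct <- network$compound_target
  hc <- network$herb_compound
  genes <- sort(unique(ct$target_gene))
  mat <- matrix(0, nrow = length(genes), ncol = length(groups),
                dimnames = list(genes, groups))
  herb_group <- setNames(network$herbs$group, network$herbs$herb_id)
  for (g in groups) {
    comps <- unique(hc$compound_id[herb_group[hc$herb_id] == g])
    sub <- ct[ct$compound_id %in% comps, , drop = FALSE]
    if (nrow(sub)) {
      tab <- table(sub$target_gene)
      mat[names(tab), g] <- as.numeric(tab)
    }
  }
  if (binary) mat[] <- as.numeric(mat > 0)
  mat
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Classic UPGMA on a symmetric distance matrix: repeatedly merge the
#' closest pair of clusters; the distance from a merged cluster to any other
#' is the size-weighted mean of its members' distances; merge height is half
#' the pair distance, so leaf-to-root path lengths are ultrametric. Ties for
#' the closest pair are broken by the lexicographically smallest
#' (sorted) label pair, making the tree deterministic.
#'
#' @param dist_mat symmetric numeric matrix with zero diagonal and
#'   dimnames giving the labels; at least 2 labels.
#' @return object of class \code{upgma_dendrogram}: list with
#'   \code{labels}, \code{merges} (list of merge records: \code{members}
#'   of the new cluster, the two \code{children} label sets and
#'   \code{height}), \code{newick} string, and \code{heights}.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$newick
#' @export
upgma <- function(dist_mat) {
  assert_that(is.matrix(dist_mat) && nrow(dist_mat) == ncol(dist_mat),
              "dist_mat must be a square matrix")
  labels <- rownames(dist_mat)
  assert_that(!is.null(labels) && identical(labels, colnames(dist_mat)),
              "dist_mat needs matching row/column labels")
  assert_that(length(labels) >= 2L, "need at least two labels")
  assert_that(all(abs(dist_mat - t(dist_mat)) < 1e-12), "dist_mat must be symmetric")
  assert_that(all(diag(dist_mat) == 0), "dist_mat diagonal must be zero")

  # active clusters: list of label vectors; parallel newick strings & heights
  clusters <- as.list(labels)
  newicks <- labels
  heights <- rep(0, length(labels))
  sizes <- rep(1L, length(labels))
  d <- dist_mat
  merges <- list()

  cluster_key <- function(members) paste(sort(members), collapse = "|")

  while (length(clusters) > 1L) {
    n <- length(clusters)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        cand <- list(i = i, j = j, dij = d[i, j],
                     key = paste(sort(c(cluster_key(clusters[[i]]),
                                        cluster_key(clusters[[j]]))),
                                 collapse = "||"))
        if (is.null(best) || cand$dij < best$dij - 1e-12 ||
            (abs(cand$dij - best$dij) <= 1e-12 && cand$key < best$key)) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    # child order convention: smaller minimum member label first
    if (min(clusters[[j]]) < min(clusters[[i]])) { tmp <- i; i <- j; j <- tmp }
    h <- best$dij / 2
    members <- c(clusters[[i]], clusters[[j]])
    merges[[length(merges) + 1L]] <- list(
      members = sort(members),
      children = list(sort(clusters[[i]]), sort(clusters[[j]])),
      height = h)

    new_newick <- sprintf("(%s:%s,%s:%s)",
                          newicks[i], format(h - heights[i], digits = 10),
                          newicks[j], format(h - heights[j], digits = 10))
    # size-weighted average distance to every other cluster
    new_d <- vapply(seq_len(n), function(k) {
      (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }, numeric(1))

    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    clusters <- c(clusters[keep], list(members))
    newicks <- c(newicks[keep], new_newick)
    heights <- c(heights[keep], h)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }

  structure(list(labels = sort(labels),
                 merges = merges,
                 heights = vapply(merges, `[[`, numeric(1), "height"),
                 newick = paste0(newicks[1], ";")),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram:", x$newick, "\n")
  invisible(x)
}

#' Topology signature of a dendrogram
#'
#' The unordered sequence of merge partitions (each merge's member set),
#' ignoring heights. Two dendrograms have the same topology iff their
#' signatures are equal.
#'
#' @param dendro an \code{upgma_dendrogram}.
#' @return sorted character vector, one entry per internal node.
#' @export
topology_signature <- function(dendro) {
  assert_that(inherits(dendro, "upgma_dendrogram"), "`dendro` must be an upgma_dendrogram")
  sort(vapply(dendro$merges, function(m) paste(m$members, collapse = "|"), ""))
}

#' Cophenetic distance matrix of a UPGMA dendrogram
#'
#' Twice the height of the lowest merge joining each label pair; under UPGMA
#' this is ultrametric.
#'
#' @param dendro an \code{upgma_dendrogram}.
#' @return symmetric numeric matrix over the dendrogram's labels.
#' @export
cophenetic_matrix <- function(dendro) {
  labs <- dendro$labels
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (mer in dendro$merges) {
    a <- mer$children[[1]]; b <- mer$children[[2]]
    m[a, b] <- 2 * mer$height
    m[b, a] <- 2 * mer$height
  }
  m
}

#' Group distance matrix from incidence profiles
#'
#' Pairwise cosine distances between the per-group columns of the incidence
#' matrix. Errors if any group has an all-zero profile (no surviving
#' targets), naming the group.
#'
#' @param network an \code{hct_network}.
#' @param binary use binary incidence instead of support counts.
#' @return symmetric distance matrix over the group labels.
#' @export
group_distances <- function(network, binary = FALSE) {
  inc <- incidence_matrix(network, binary = binary)
  groups <- colnames(inc)
  zero <- groups[colSums(inc) == 0]
  assert_that(length(zero) == 0L,
              "group(s) with all-zero target profile: ", paste(zero, collapse = ", "))
  d <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i < j) {
        d[i, j] <- d[j, i] <- cosine_distance(inc[, i], inc[, j])
      }
    }
  }
  d
}

#' Cluster constitution types across per-compound target caps
#'
#' Re-applies each cap to the (uncapped) network, recomputes the group
#' incidence profiles and their cosine distances, and clusters with UPGMA.
#' Reports whether the tree topology (unordered merge-partition sequence)
#' is identical across all caps — the robustness check that the similarity
#' structure of the types is not an artefact of the cap.
#'
#' @param network an \code{hct_network}; build it with \code{cap =
#'   "unlimited"} so every finite cap can be derived from it.
#' @param caps list/vector of caps (positive integers or
#'   \code{"unlimited"}).
#' @param binary use binary incidence profiles.
#' @return list of class \code{cap_clustering}: \code{dendrograms} (named by
#'   cap), \code{distances} (named list of matrices), and
#'   \code{same_topology} (logical).
#' @export
cluster_groups <- function(network, caps = list(10, 50, 100, 500, "unlimited"),
                           binary = FALSE) {
  assert_that(length(caps) >= 1L, "caps must be non-empty")
  caps <- as.list(caps)
  cap_names <- vapply(caps, as.character, "")  # duplicates allowed
  dendros <- setNames(vector("list", length(caps)), cap_names)
  dists <- setNames(vector("list", length(caps)), cap_names)
  for (i in seq_along(caps)) {
    net_c <- apply_cap(network, caps[[i]])
    d <- group_distances(net_c, binary = binary)
    dists[[i]] <- d
    dendros[[i]] <- upgma(d)
  }
  sigs <- lapply(dendros, topology_signature)
  same <- all(vapply(sigs, identical, logical(1), y = sigs[[1]]))
  structure(list(dendrograms = dendros, distances = dists,
                 same_topology = same),
            class = "cap_clustering")
}

#' @export
print.cap_clustering <- function(x, ...) {
  cat("Cap-robustness clustering over", length(x$dendrograms), "caps\n")
  for (nm in names(x$dendrograms)) {
    cat(sprintf("  cap %-9s %s\n", nm, x$dendrograms[[nm]]$newick))
  }
  cat("  same topology across caps:", x$same_topology, "\n")
  invisible(x)
}
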