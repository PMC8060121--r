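#' Load a constitution-typed herb catalog
#'
#' Reads a tab-separated herb catalog with columns \code{herb_id},
#' \code{group}, \code{local_name}, \code{latin_name}. The packaged catalog
#' (\code{system.file("extdata", "herb_catalog.tsv", package = "scnetpharm")})
#' lists the 28 herbs that preserve and strengthen the requisite energy of
#' each Sasang constitution type: 8 SE, 8 SY, 8 TE and 4 TY herbs.
#'
#' @param path path to the catalog TSV ('#' lines are comments).
#' @param groups character vector of admissible group labels, in the order
#'   used for all downstream output. Defaults to the four constitution types.
#' @return data.frame of class \code{herb_catalog} with one row per herb and
#'   a \code{groups} attribute fixing the group order.
#' @examples
#' cat_path <- system.file("extdata", "herb_catalog.tsv", package = "scnetpharm")
#' herbs <- load_herb_catalog(cat_path)
#' table(herbs$group)
#' @export
load_herb_catalog <- function(path, groups = c("SE", "SY", "TE", "TY")) {
  df <- read_tsv_checked(path, c("herb_id", "group", "local_name", "latin_name"))
  if (nrow(df)) {
    dup <- df$herb_id[duplicated(df$herb_id)]
    assert_that(length(dup) == 0L,
                "duplicate herb_id in catalog: ", paste(unique(dup), collapse = ", "))
    bad <- setdiff(unique(df$group), groups)
    assert_that(length(bad) == 0L,
                "unknown group label(s) in catalog: ", paste(bad, collapse = ", "),
                " (expected one of ", paste(groups, collapse = ", "), ")")
  }
  structure(df, groups = groups, class = c("herb_catalog", "data.frame"))
}

#' Build a filtered herb-compound-target network
#'
#' Assembles the tripartite network from an herb catalog, an herb-to-compound
#' edge table and a scored compound-to-target edge table, then applies the
#' two filters used throughout the analysis: compound-target edges are kept
#' only when their confidence score strictly exceeds \code{score_threshold}
#' (default 700 on the 0-1000 scale), and each compound keeps at most
#' \code{cap} target edges (default 10), retaining the highest-scoring ones
#' with ties broken by lexicographically smallest gene symbol. Compounds left
#' without any surviving target remain in the network as flagged orphan nodes.
#'
#' Gene symbols are upper-cased on load. Compound-target rows whose compound
#' never appears in the herb-compound table are dropped (and counted in the
#' filter log): they cannot be traced to any catalogued herb.
#'
#' @param herbs an \code{herb_catalog} from \code{\link{load_herb_catalog}}.
#' @param herb_compound path to a TSV with columns \code{herb_id},
#'   \code{compound_id}, or an equivalent data.frame.
#' @param compound_target path to a TSV with columns \code{compound_id},
#'   \code{target_gene}, \code{score}, or an equivalent data.frame.
#' @param score_threshold numeric in [0, 1000]; edges with score strictly
#'   greater than this survive.
#' @param cap positive integer, or \code{"unlimited"} for no per-compound cap.
#' @param verbose emit filter-stage counts as messages.
#' @return an object of class \code{hct_network}: a list with the herb
#'   catalog, both edge tables after filtering, the compound node set with an
#'   \code{orphaned} flag vector, the filter settings, and a
#'   \code{filter_log} data.frame of edge counts per stage.
#' @seealso \code{\link{apply_cap}} to re-cap an existing network,
#'   \code{\link{collect_targets}} for the per-group gene sets.
#' @export
build_network <- function(herbs, herb_compound, compound_target,
                          score_threshold = 700, cap = 10, verbose = FALSE) {
  assert_that(inherits(herbs, "herb_catalog"),
              "`herbs` must come from load_herb_catalog()")
  assert_that(is.numeric(score_threshold) && length(score_threshold) == 1L &&
                score_threshold >= 0 && score_threshold <= 1000,
              "score_threshold must be a single number in [0, 1000]")
  check_cap(cap)

  hc <- if (is.data.frame(herb_compound)) herb_compound else
    read_tsv_checked(herb_compound, c("herb_id", "compound_id"))
  ct <- if (is.data.frame(compound_target)) compound_target else
    read_tsv_checked(compound_target, c("compound_id", "target_gene", "score"))
  hc <- hc[, c("herb_id", "compound_id")]
  ct <- ct[, c("compound_id", "target_gene", "score")]

  unknown <- setdiff(unique(hc$herb_id), herbs$herb_id)
  assert_that(length(unknown) == 0L,
              "herb-compound edge(s) reference unknown herb(s): ",
              paste(unknown, collapse = ", "))
  hc <- unique(hc)

  score <- suppressWarnings(as.numeric(ct$score))
  assert_that(!anyNA(score), "malformed (non-numeric) score in compound-target table")
  assert_that(all(score >= 0 & score <= 1000), "compound-target scores must lie in [0, 1000]")
  ct$score <- score
  ct$target_gene <- normalize_gene(ct$target_gene)
  key <- paste(ct$compound_id, ct$target_gene, sep = "\r")
  assert_that(!anyDuplicated(key),
              "duplicate (compound_id, target_gene) pair(s) in compound-target table")

  log <- data.frame(stage = "input", edges = nrow(ct), stringsAsFactors = FALSE)
  compounds <- sort(unique(hc$compound_id))
  known <- ct$compound_id %in% compounds
  ct <- ct[known, , drop = FALSE]
  log <- rbind(log, data.frame(stage = "traceable_compound", edges = nrow(ct)))

  ct <- ct[ct$score > score_threshold, , drop = FALSE]
  log <- rbind(log, data.frame(stage = "score_filter", edges = nrow(ct)))

  ct <- cap_edges(ct, cap)
  log <- rbind(log, data.frame(stage = "cap_filter", edges = nrow(ct)))
  rownames(ct) <- NULL

  if (verbose) {
    for (i in seq_len(nrow(log))) {
      message(sprintf("[build_network] %-18s %d edges", log$stage[i], log$edges[i]))
    }
  }

  structure(list(
    herbs = herbs,
    groups = attr(herbs, "groups"),
    herb_compound = hc,
    compound_target = ct,
    compounds = compounds,
    orphaned = setdiff(compounds, unique(ct$compound_id)),
    score_threshold = score_threshold,
    cap = cap,
    filter_log = log
  ), class = "hct_network")
}

check_cap <- function(cap) {
  ok <- (is.character(cap) && identical(cap, "unlimited")) ||
    (is.numeric(cap) && length(cap) == 1L && cap >= 1 && cap == floor(cap))
  assert_that(ok, "cap must be a positive integer or \"unlimited\"")
}

# Per-compound top-`cap` edges by score, ties by lexicographic target_gene
# ascending. Deterministic for any input order.
cap_edges <- function(ct, cap) {
  if (identical(cap, "unlimited") || nrow(ct) == 0L) {
    return(ct[order(ct$compound_id, ct$target_gene), , drop = FALSE])
  }
  ord <- order(ct$compound_id, -ct$score, ct$target_gene)
  ct <- ct[ord, , drop = FALSE]
  rank_in_compound <- stats::ave(seq_len(nrow(ct)), ct$compound_id,
                                 FUN = seq_along)
  ct <- ct[rank_in_compound <= cap, , drop = FALSE]
  ct[order(ct$compound_id, ct$target_gene), , drop = FALSE]
}

#' Re-apply a per-compound target cap to an existing network
#'
#' Recomputes the cap filter (top-\code{cap} targets per compound by score,
#' ties by gene symbol) on the network's surviving compound-target edges.
#' Used by \code{\link{cluster_groups}} to test robustness across caps; for
#' that reason the input is usually a network built with
#' \code{cap = "unlimited"}. Capping is idempotent and monotone: a smaller
#' cap always yields a subset of the edges kept by a larger one.
#'
#' @param network an \code{hct_network}.
#' @param cap positive integer or \code{"unlimited"}.
#' @return a new \code{hct_network} with the cap applied.
#' @export
apply_cap <- function(network, cap) {
  assert_that(inherits(network, "hct_network"), "`network` must be an hct_network")
  check_cap(cap)
  ct <- cap_edges(network$compound_target, cap)
  rownames(ct) <- NULL
  network$compound_target <- ct
  network$orphaned <- setdiff(network$compounds, unique(ct$compound_id))
  network$cap <- cap
  network$filter_log <- rbind(network$filter_log,
                              data.frame(stage = "recap", edges = nrow(ct)))
  network
}

#' @export
print.hct_network <- function(x, ...) {
  cat("Herb-compound-target network\n")
  cat(sprintf("  herbs: %d (%s)\n", nrow(x$herbs),
              paste(sprintf("%s=%d", x$groups,
                            as.integer(table(factor(x$herbs$group, x$groups)))),
                    collapse = ", ")))
  cat(sprintf("  compounds: %d (%d orphaned)\n",
              length(x$compounds), length(x$orphaned)))
  cat(sprintf("  compound-target edges: %d (score > %s, cap %s)\n",
              nrow(x$compound_target), format(x$score_threshold),
              as.character(x$cap)))
  invisible(x)
}

#' Serialize / restore a network as JSON
#'
#' The JSON document holds the node lists (herbs with groups, compounds with
#' orphan flags, target genes) and both edge lists, plus the filter settings
#' — enough to reconstruct the network exactly.
#'
#' @param network an \code{hct_network}.
#' @param path output file.
#' @return \code{write_network_json} returns \code{path} invisibly;
#'   \code{read_network_json} returns the restored \code{hct_network}.
#' @export
write_network_json <- function(network, path) {
  assert_that(inherits(network, "hct_network"), "`network` must be an hct_network")
  doc <- list(
    groups = network$groups,
    herbs = network$herbs[, c("herb_id", "group", "local_name", "latin_name")],
    compounds = data.frame(compound_id = network$compounds,
                           orphaned = network$compounds %in% network$orphaned),
    targets = sort(unique(network$compound_target$target_gene)),
    herb_compound = network$herb_compound,
    compound_target = network$compound_target,
    score_threshold = network$score_threshold,
    cap = network$cap
  )
  jsonlite::write_json(doc, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  herbs <- structure(as.data.frame(doc$herbs, stringsAsFactors = FALSE),
                     groups = doc$groups, class = c("herb_catalog", "data.frame"))
  ct <- as.data.frame(doc$compound_target, stringsAsFactors = FALSE)
  if (!nrow(ct)) ct <- data.frame(compound_id = character(), target_gene = character(),
                                  score = numeric())
  hc <- as.data.frame(doc$herb_compound, stringsAsFactors = FALSE)
  cap <- doc$cap
  if (is.numeric(cap)) cap <- as.integer(cap)
  structure(list(
    herbs = herbs, groups = doc$groups,
    herb_compound = hc, compound_target = ct,
    compounds = doc$compounds$compound_id,
    orphaned = doc$compounds$compound_id[doc$compounds$orphaned],
    score_threshold = doc$score_threshold, cap = cap,
    filter_log = data.frame(stage = "restored", edges = nrow(ct))
  ), class = "hct_network")
}
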