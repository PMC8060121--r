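#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated as
#' \code{term_id <TAB> description <TAB> gene1 <TAB> gene2 ...}.
#' Gene symbols are upper-cased; within-term duplicates are dropped.
#'
#' @param path GMT file path.
#' @param universe optional explicit reference universe (character vector of
#'   gene symbols); defaults to the union of all genes in the file.
#' @return object of class \code{gene_set_library}: list with \code{terms}
#'   (named list of gene vectors), \code{term_names} (named character),
#'   \code{universe} and \code{N = length(universe)}.
#' @export
read_gmt <- function(path, universe = NULL) {
  assert_that(file.exists(path), "GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  assert_that(length(lines) > 0, "empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  assert_that(!anyDuplicated(ids), "duplicate term ids in GMT: ", path)
  term_names <- setNames(vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", ""), ids)
  terms <- setNames(lapply(parts, function(p) {
    unique(normalize_gene(p[-(1:2)]))
  }), ids)
  gene_set_library(terms, term_names, universe)
}

#' Construct a gene-set library
#'
#' @param terms named list: term_id -> character vector of gene symbols.
#' @param term_names named character vector of descriptions (optional).
#' @param universe reference universe; defaults to the union of term genes.
#' @return a \code{gene_set_library}.
#' @export
gene_set_library <- function(terms, term_names = NULL, universe = NULL) {
  assert_that(length(terms) > 0, "library must contain at least one term")
  terms <- lapply(terms, function(g) unique(normalize_gene(g)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(terms, use.names = FALSE)))
  } else {
    universe <- sort(unique(normalize_gene(universe)))
    outside <- setdiff(unlist(terms, use.names = FALSE), universe)
    assert_that(length(outside) == 0L,
                "term gene(s) outside the declared universe: ",
                paste(head(outside, 5), collapse = ", "))
  }
  if (is.null(term_names)) term_names <- setNames(names(terms), names(terms))
  structure(list(terms = terms, term_names = term_names,
                 universe = universe, N = length(universe)),
            class = "gene_set_library")
}

#' Expected in-list count for a category
#'
#' The number of genes of an annotation category expected in a target list
#' under proportional sampling from the reference universe:
#' \code{n_mapped * K / N}, where \code{K} is the category's reference-list
#' count and \code{N} the universe size.
#'
#' @param n_mapped number of target-list genes mapped to the universe.
#' @param K reference-list count of the category.
#' @param N universe size.
#' @return expected count (numeric).
#' @export
expected_count <- function(n_mapped, K, N) {
  assert_that(all(N > 0), "N must be positive")
  assert_that(all(K >= 0 & K <= N), "K must lie in [0, N]")
  assert_that(all(n_mapped >= 0), "n_mapped must be nonnegative")
  n_mapped * K / N
}

#' One-sided overrepresentation p-value
#'
#' Probability of observing \code{k} or more category genes in a list of
#' \code{n} genes drawn from a universe of \code{N} with \code{K} category
#' members: the upper hypergeometric tail \eqn{P(X \ge k)} (Fisher's exact
#' one-sided test), or a one-sided binomial tail with success probability
#' \code{K/N} when \code{method = "binomial"}.
#'
#' @param k observed in-list category count.
#' @param K reference category count.
#' @param n list size.
#' @param N universe size.
#' @param method \code{"fisher"} (hypergeometric, default) or
#'   \code{"binomial"}.
#' @return p-value in (0, 1].
#' @export
fisher_overrep <- function(k, K, n, N, method = c("fisher", "binomial")) {
  method <- match.arg(method)
  assert_that(all(k >= 0) && all(K >= 0) && all(n >= 0) && all(N > 0),
              "counts must be nonnegative, N positive")
  assert_that(all(k <= K) && all(k <= n) && all(K <= N) && all(n <= N),
              "inconsistent contingency counts (need k <= K, k <= n, K,n <= N)")
  if (method == "fisher") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1),
#' returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Dense membership matrix universe x terms for fast repeated k counting.
membership_matrix <- function(library) {
  mat <- matrix(FALSE, nrow = library$N, ncol = length(library$terms),
                dimnames = list(library$universe, names(library$terms)))
  for (t in names(library$terms)) {
    mat[library$terms[[t]], t] <- TRUE
  }
  mat
}

#' Rank-deviation Z-scores and combined scores
#'
#' Reconstruction of the PANTHER/Enrichr-style term-ranking statistic: for
#' \code{R_cal} random gene lists of the same size as the target list, all
#' terms are ranked by their overrepresentation p-value; each term's
#' expected rank (mean) and rank spread (sd) under these random lists give
#' \eqn{z = (r_{obs} - \mu) / \sigma} (negative z = ranked better than
#' expected by chance). The combined score is \eqn{z \times \ln p_{obs}},
#' positive when a term is both significant and better-ranked than
#' expected, and 0 whenever \eqn{p_{obs} = 1} or \eqn{z = 0}. A term whose
#' random ranks never vary gets z = 0 with a warning.
#'
#' @param library a \code{gene_set_library}.
#' @param target_genes character vector of gene symbols (the observed list).
#' @param p_obs named numeric vector of observed p-values, one per library
#'   term (names must match the library's term ids).
#' @param R_cal number of random calibration lists (>= 30).
#' @param seed optional integer seed.
#' @param method test passed through to \code{\link{fisher_overrep}}.
#' @return data.frame with columns \code{term_id}, \code{z},
#'   \code{combined}.
#' @export
rank_z_and_combined <- function(library, target_genes, p_obs, R_cal = 200,
                                seed = NULL, method = "fisher") {
  assert_that(inherits(library, "gene_set_library"), "`library` must be a gene_set_library")
  assert_that(R_cal >= 30, "R_cal must be at least 30")
  term_ids <- names(library$terms)
  assert_that(all(term_ids %in% names(p_obs)), "p_obs must cover every library term")
  p_obs <- p_obs[term_ids]
  if (!is.null(seed)) set.seed(seed)

  mapped <- intersect(normalize_gene(target_genes), library$universe)
  n <- length(mapped)
  assert_that(n > 0, "no target genes map to the library universe")
  memb <- membership_matrix(library)
  K <- colSums(memb)

  r_obs <- rank(p_obs, ties.method = "average")
  rank_sum <- rank_sq_sum <- setNames(numeric(length(term_ids)), term_ids)
  for (r in seq_len(R_cal)) {
    draw <- sample(library$universe, n)
    k_r <- colSums(memb[draw, , drop = FALSE])
    p_r <- fisher_overrep(k_r, K, n, library$N, method = method)
    rk <- rank(p_r, ties.method = "average")
    rank_sum <- rank_sum + rk
    rank_sq_sum <- rank_sq_sum + rk^2
  }
  mu <- rank_sum / R_cal
  sigma <- sqrt(pmax(0, (rank_sq_sum - R_cal * mu^2) / (R_cal - 1)))
  z <- ifelse(sigma > 0, (r_obs - mu) / sigma, 0)
  if (any(sigma == 0)) {
    warning("term(s) with zero rank spread under calibration; z set to 0: ",
            paste(term_ids[sigma == 0], collapse = ", "))
  }
  combined <- z * log(p_obs)
  data.frame(term_id = term_ids, z = unname(z), combined = unname(combined),
             stringsAsFactors = FALSE)
}

#' Gene-set overrepresentation analysis
#'
#' PANTHER-style overrepresentation of library terms in a target gene list:
#' per term the reference count K, in-list count k, expected count
#' \code{n_mapped * K / N}, one-sided p-value
#' (\code{\link{fisher_overrep}}), BH-adjusted p, rank-deviation z and
#' combined score (\code{\link{rank_z_and_combined}}). Rows are sorted by
#' combined score, descending. Target genes absent from the universe are
#' dropped before testing (\code{n_mapped} counts only mapped genes); if no
#' gene maps, an error lists the unmapped input.
#'
#' @param library a \code{gene_set_library}.
#' @param target_genes character vector of gene symbols.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param R_cal calibration lists for the z-score (default 200).
#' @param seed optional integer seed for the calibration draw.
#' @param method \code{"fisher"} or \code{"binomial"}.
#' @return data.frame of class \code{enrichment_result} with one row per
#'   term: \code{term_id}, \code{term_name}, \code{ref_count},
#'   \code{target_count}, \code{expected}, \code{p}, \code{p_adj}, \code{z},
#'   \code{combined}, \code{significant}; attributes \code{n_mapped},
#'   \code{N}, \code{alpha}.
#' @export
overrepresentation <- function(library, target_genes, alpha = 0.05,
                               R_cal = 200, seed = NULL,
                               method = c("fisher", "binomial")) {
  method <- match.arg(method)
  assert_that(inherits(library, "gene_set_library"), "`library` must be a gene_set_library")
  genes <- unique(normalize_gene(target_genes))
  mapped <- intersect(genes, library$universe)
  if (!length(mapped)) {
    stop("no target genes map to the annotation universe; unmapped input: ",
         paste(head(genes, 10), collapse = ", "), call. = FALSE)
  }
  n <- length(mapped)
  term_ids <- names(library$terms)
  K <- vapply(library$terms, length, integer(1))
  k <- vapply(library$terms, function(g) sum(mapped %in% g), integer(1))
  p <- fisher_overrep(k, K, n, library$N, method = method)
  p <- setNames(pmin(p, 1), term_ids)
  p_adj <- bh_adjust(p)
  zc <- rank_z_and_combined(library, mapped, p, R_cal = R_cal, seed = seed,
                            method = method)
  res <- data.frame(term_id = term_ids,
                    term_name = unname(library$term_names[term_ids]),
                    ref_count = unname(K), target_count = unname(k),
                    expected = expected_count(n, unname(K), library$N),
                    p = unname(p), p_adj = unname(p_adj),
                    z = zc$z, combined = zc$combined,
                    significant = unname(p_adj) < alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$combined, res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, n_mapped = n, N = library$N, alpha = alpha,
            class = c("enrichment_result", "data.frame"))
}
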