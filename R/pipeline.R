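#' Run the full constitution-stratified analysis
#'
#' End-to-end orchestration: build the filtered herb-compound-target network,
#' collect per-type target sets and overlap counts, cluster the types across
#' per-compound target caps, run the exclusivity permutation test, per-type
#' GO overrepresentation, first-level category profiles with their Euclidean
#' distance matrix, and ICD-10 disease-chapter profiles. Every stage writes
#' its result to \code{out_dir} and logs row counts to standard error; a
#' machine-readable \code{summary.json} collects the headline numbers. A
#' stage failure aborts with the stage name and cause.
#'
#' @param inputs named list/vector of input paths: \code{herb_catalog},
#'   \code{herb_compound}, \code{compound_target}, \code{go_slim},
#'   \code{first_level}, \code{gda}, \code{icd_map} (e.g. the \code{paths}
#'   element of \code{\link{generate_bundle}}).
#' @param out_dir output directory.
#' @param score_threshold interaction-confidence cutoff (default 700).
#' @param cap per-compound target cap for the main analysis (default 10).
#' @param caps caps for the clustering robustness check.
#' @param R permutations for the exclusivity test.
#' @param R_cal calibration lists for the enrichment z-score.
#' @param alpha adjusted-p significance level.
#' @param k top-scored diseases per gene.
#' @param seed integer seed driving the permutation and calibration draws.
#' @param verbose log stage progress to standard error (default TRUE).
#' @return (invisibly) the summary list, also written as
#'   \code{summary.json}.
#' @export
run_all <- function(inputs, out_dir,
                    score_threshold = 700, cap = 10,
                    caps = list(10, 50, 100, 500, "unlimited"),
                    R = 999, R_cal = 200, alpha = 0.05, k = 3,
                    seed = 1, verbose = TRUE) {
  need <- c("herb_catalog", "herb_compound", "compound_target",
            "go_slim", "first_level", "gda", "icd_map")
  missing <- setdiff(need, names(inputs))
  assert_that(length(missing) == 0L,
              "missing input path(s): ", paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[run_all] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## network construction
  net <- stage("network", {
    herbs <- load_herb_catalog(inputs[["herb_catalog"]])
    full <- build_network(herbs, inputs[["herb_compound"]],
                          inputs[["compound_target"]],
                          score_threshold = score_threshold, cap = "unlimited")
    full
  })
  net_capped <- apply_cap(net, cap)
  write_network_json(net_capped, file.path(out_dir, "network.json"))
  say("network: %d herbs, %d compounds, %d edges at cap %s",
      nrow(net$herbs), length(net$compounds), nrow(net_capped$compound_target),
      as.character(cap))

  ## target sets + overlaps
  coll <- stage("targets", collect_targets(net_capped))
  targets_df <- do.call(rbind, lapply(coll$groups, function(g) {
    if (!length(coll$sets[[g]])) return(NULL)
    data.frame(group = g, gene = coll$sets[[g]], stringsAsFactors = FALSE)
  }))
  write_tsv_plain(targets_df, file.path(out_dir, "targets.tsv"))
  ov <- stage("overlaps", overlap_table(coll))
  write_tsv_plain(ov$regions, file.path(out_dir, "overlaps.tsv"))
  say("targets: %s; union %d",
      paste(sprintf("%s=%d", coll$groups, lengths(coll$sets[coll$groups])),
            collapse = ", "), ov$union_size)

  ## clustering across caps
  clust <- stage("clustering", cluster_groups(net, caps = caps))
  for (nm in names(clust$dendrograms)) {
    writeLines(clust$dendrograms[[nm]]$newick,
               file.path(out_dir, sprintf("dendrogram_cap_%s.nwk", nm)))
  }
  say("clustering: same topology across caps = %s", clust$same_topology)

  ## permutation test
  perm <- stage("permutation", permutation_test(net_capped, R = R, seed = seed))
  perm_df <- data.frame(group = names(perm$observed),
                        observed = unname(perm$observed),
                        p = unname(perm$p_values), R = R, seed = seed,
                        stringsAsFactors = FALSE)
  write_tsv_plain(perm_df, file.path(out_dir, "perm.tsv"))
  say("permutation: %s",
      paste(sprintf("%s p=%.4g", perm_df$group, perm_df$p), collapse = ", "))

  ## enrichment per group
  library_go <- stage("enrichment", read_gmt(inputs[["go_slim"]]))
  sig_counts <- setNames(integer(length(coll$groups)), coll$groups)
  for (g in coll$groups) {
    res <- stage(paste0("enrichment_", g),
                 overrepresentation(library_go, coll$sets[[g]], alpha = alpha,
                                    R_cal = R_cal, seed = seed))
    sig_counts[[g]] <- sum(res$significant)
    write_tsv_plain(as.data.frame(res),
                    file.path(out_dir, sprintf("enrich_%s.tsv", g)))
  }
  say("enrichment: significant terms %s",
      paste(sprintf("%s=%d", names(sig_counts), sig_counts), collapse = ", "))

  ## first-level category profiles + distances
  fl <- stage("category_profiles", read_gmt(inputs[["first_level"]]))
  profiles <- lapply(coll$groups, function(g) {
    category_profile(fl, coll$sets[[g]], group = g)
  })
  dmat <- stage("profile_distances", profile_distances(profiles))
  write_tsv_plain(data.frame(group = rownames(dmat), as.data.frame(dmat),
                             check.names = FALSE),
                  file.path(out_dir, "dist.tsv"))

  ## disease profiles
  dp <- stage("disease_profiles", {
    gda <- read_gene_disease(inputs[["gda"]])
    icd <- read_icd_map(inputs[["icd_map"]])
    suppressWarnings(disease_profile(coll, gda, icd, k = k))
  })
  dp_df <- do.call(rbind, lapply(dp, function(p) {
    data.frame(group = p$group, chapter = names(p$proportions),
               proportion = unname(p$proportions), total = p$total,
               stringsAsFactors = FALSE)
  }))
  write_tsv_plain(dp_df, file.path(out_dir, "disease_profiles.tsv"))

  summary <- list(
    seed = seed,
    settings = list(score_threshold = score_threshold, cap = cap,
                    caps = lapply(caps, as.character), R = R, R_cal = R_cal,
                    alpha = alpha, k = k),
    target_counts = as.list(lengths(coll$sets)),
    union_size = ov$union_size,
    pairwise_shared = ov$pairwise,
    exclusive_counts = as.list(ov$exclusive),
    permutation_p = as.list(perm$p_values),
    significant_terms = as.list(sig_counts),
    clustering_same_topology = clust$same_topology,
    dendrogram_default = clust$dendrograms[[as.character(cap)]]$newick %||%
      clust$dendrograms[[1]]$newick,
    category_distance_max = max(dmat),
    modal_chapter = lapply(dp, function(p) {
      if (p$total == 0) return(NA)
      names(p$proportions)[which.max(p$proportions)]
    }))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  say("summary written to %s", file.path(out_dir, "summary.json"))
  invisible(summary)
}
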