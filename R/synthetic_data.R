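#' Configuration for the synthetic-data generator
#'
#' Builds a validated configuration for \code{\link{generate_bundle}}. The
#' defaults emulate the study conditions at desk scale: 28 herbs (8/8/8/4
#' across SE/SY/TE/TY), roughly 300 compounds, a 1500-gene universe, and a
#' planted overlap structure in which SE and SY share the largest fraction
#' of their target pools while TY is nearly isolated — the qualitative
#' structure the downstream clustering and exclusivity analyses are designed
#' to detect.
#'
#' @param groups ordered group labels.
#' @param herb_counts herbs per group (named or positional).
#' @param pool_sizes planted target-pool size per group; the default sizes
#'   preserve the SE > SY > TE > TY ordering of the real target-set sizes at
#'   roughly 0.4 scale.
#' @param overlap symmetric matrix (groups x groups) giving, for each pair,
#'   the fraction of the smaller pool planted as shared between exactly that
#'   pair; pairwise allocations are disjoint (no planted triple overlaps).
#' @param structure \code{"planted"} (pools + overlaps as configured) or
#'   \code{"null"} (every compound draws targets uniformly from the
#'   universe; no exclusivity structure).
#' @param compounds_per_herb,targets_per_compound means of 1-truncated
#'   Poisson counts.
#' @param promiscuous_prob,promiscuous_mean a fraction of compounds is
#'   "promiscuous" with a much larger mean target count, so that the
#'   per-compound target cap actually binds (the reason the cap exists).
#' @param max_targets_per_compound hard ceiling on targets drawn per
#'   compound (before any analysis-time cap).
#' @param shared_compound_prob probability that a herb reuses a compound
#'   already created for its own group (cross-group compound sharing is not
#'   generated, so planted pools are exactly recoverable).
#' @param frac_above_700 fraction of interaction scores drawn above the
#'   700/1000 confidence threshold; scores follow a Beta distribution
#'   rescaled to [0, 1000], sampled from the matching tail.
#' @param score_beta shape parameters of the score Beta distribution.
#' @param universe_size annotation/reference universe size N.
#' @param n_first_level,terms_per_category,term_size_mean first-level
#'   category count and specific-term library shape.
#' @param multi_category_prob probability a gene belongs to a second
#'   first-level category.
#' @param category_skew named list group -> first-level category id that
#'   dominates that group's pool genes, with element \code{prob} giving the
#'   assignment probability (see default).
#' @param planted_term list(group, size, effect): a specific term whose
#'   genes are drawn with fraction \code{effect} from the group's pool, so
#'   the group's target list is strongly enriched for it.
#' @param diseases_per_gene mean (1-truncated Poisson) diseases per gene.
#' @param diseases_per_chapter synthetic diseases generated per ICD-10
#'   chapter.
#' @param chapter_skew named character vector group -> ICD-10 chapter that
#'   dominates that group's gene-disease associations.
#' @param chapter_skew_prob target share of a skewed group's disease draws
#'   falling in its planted chapter.
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(
    groups = c("SE", "SY", "TE", "TY"),
    herb_counts = c(SE = 8, SY = 8, TE = 8, TY = 4),
    pool_sizes = c(SE = 150, SY = 90, TE = 75, TY = 45),
    overlap = NULL,
    structure = c("planted", "null"),
    compounds_per_herb = 10,
    targets_per_compound = 4,
    promiscuous_prob = 0.1,
    promiscuous_mean = 18,
    max_targets_per_compound = 30,
    shared_compound_prob = 0.1,
    frac_above_700 = 0.7,
    score_beta = c(4, 2),
    universe_size = 1500,
    n_first_level = 8,
    terms_per_category = 6,
    term_size_mean = 25,
    multi_category_prob = 0.25,
    category_skew = list(TY = list(category = "FL02", prob = 0.7)),
    planted_term = list(group = "SE", size = 30, effect = 0.8),
    diseases_per_gene = 5,
    diseases_per_chapter = 10,
    chapter_skew = c(SE = "Diseases of the digestive system",
                     SY = "Diseases of the nervous system",
                     TE = "Endocrine, nutritional and metabolic diseases",
                     TY = "Congenital malformations, deformations and chromosomal abnormalities"),
    chapter_skew_prob = 0.6) {
  structure_kind <- match.arg(structure)
  if (is.null(names(herb_counts))) names(herb_counts) <- groups
  if (is.null(names(pool_sizes))) names(pool_sizes) <- groups
  if (is.null(overlap)) {
    overlap <- matrix(0, length(groups), length(groups),
                      dimnames = list(groups, groups))
    set_pair <- function(a, b, v) {
      if (all(c(a, b) %in% groups)) overlap[a, b] <<- overlap[b, a] <<- v
    }
    set_pair("SE", "SY", 0.30)
    set_pair("SE", "TE", 0.15)
    set_pair("SY", "TE", 0.15)
    set_pair("SE", "TY", 0.05)
    set_pair("TE", "TY", 0.02)
  }
  assert_that(all(overlap >= 0 & overlap <= 1), "overlap fractions must lie in [0, 1]")
  assert_that(all(abs(overlap - t(overlap)) < 1e-12), "overlap matrix must be symmetric")
  assert_that(all(herb_counts[groups] >= 1), "each group needs at least one herb")
  assert_that(frac_above_700 >= 0 && frac_above_700 <= 1,
              "frac_above_700 must lie in [0, 1]")
  assert_that(shared_compound_prob >= 0 && shared_compound_prob <= 1,
              "shared_compound_prob must lie in [0, 1]")
  cfg <- list(groups = groups, herb_counts = herb_counts[groups],
              pool_sizes = pool_sizes[groups], overlap = overlap[groups, groups],
              structure = structure_kind,
              compounds_per_herb = compounds_per_herb,
              targets_per_compound = targets_per_compound,
              promiscuous_prob = promiscuous_prob,
              promiscuous_mean = promiscuous_mean,
              max_targets_per_compound = max_targets_per_compound,
              shared_compound_prob = shared_compound_prob,
              frac_above_700 = frac_above_700, score_beta = score_beta,
              universe_size = universe_size, n_first_level = n_first_level,
              terms_per_category = terms_per_category,
              term_size_mean = term_size_mean,
              multi_category_prob = multi_category_prob,
              category_skew = category_skew, planted_term = planted_term,
              diseases_per_gene = diseases_per_gene,
              diseases_per_chapter = diseases_per_chapter,
              chapter_skew = chapter_skew,
              chapter_skew_prob = chapter_skew_prob)
  class(cfg) <- "synthetic_config"
  cfg
}

# 1-truncated Poisson draw with mean `mean` (approximately: 1 + Pois(mean-1)).
rpois_trunc1 <- function(n, mean) 1L + stats::rpois(n, max(mean - 1, 0))

# Interaction scores on [0, 1000]: Beta(a, b) sampled from above/below the
# 0.7 quantile cut so the configured fraction lies above 700.
draw_scores <- function(n, cfg, force_above = FALSE) {
  a <- cfg$score_beta[1]; b <- cfg$score_beta[2]
  p_cut <- stats::pbeta(0.7, a, b)
  above <- if (force_above) rep(TRUE, n) else stats::runif(n) < cfg$frac_above_700
  u <- stats::runif(n)
  q <- ifelse(above, p_cut + u * (1 - p_cut), u * p_cut)
  round(1000 * stats::qbeta(q, a, b), 2)
}

#' Generate a synthetic analysis bundle
#'
#' Writes every input file the pipeline consumes — herb catalog,
#' herb-compound and scored compound-target edge tables, a two-tier GMT
#' annotation library (first-level categories and specific terms), a
#' gene-disease score table, and a disease-to-ICD-10-chapter map — together
#' with a ground-truth manifest (JSON) recording the planted per-group gene
#' pools, the overlap design, the planted enriched term and the per-group
#' chapter skews. All identifiers are synthetic. With a fixed seed the
#' bundle is byte-identical across runs.
#'
#' In the \code{"planted"} structure, the generator guarantees that every
#' planted pool gene is supported by at least one interaction scoring above
#' 700, so that \code{\link{collect_targets}} on the network built with
#' \code{score_threshold = 700, cap = "unlimited"} recovers the pools
#' exactly.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return list of class \code{synthetic_bundle}: \code{paths} (named file
#'   paths), \code{manifest} (the ground truth, also written as
#'   \code{manifest.json}).
#' @export
generate_bundle <- function(config = synthetic_config(), seed = 1,
                            out_dir = tempfile("scnp_bundle_")) {
  assert_that(inherits(config, "synthetic_config"), "`config` must be a synthetic_config")
  cfg <- config
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- cfg$groups
  n_g <- length(groups)

  gene_ids <- sprintf("G%05d", seq_len(cfg$universe_size))

  ## --- planted target pools -------------------------------------------------
  pair_list <- list()
  if (n_g >= 2) {
    for (i in seq_len(n_g - 1)) for (j in seq(i + 1, n_g)) {
      a <- groups[i]; b <- groups[j]
      n_shared <- round(cfg$overlap[a, b] * min(cfg$pool_sizes[[a]], cfg$pool_sizes[[b]]))
      if (n_shared > 0) pair_list[[paste(a, b, sep = "+")]] <- c(a, b, n_shared)
    }
  }
  shared_per_group <- setNames(rep(0L, n_g), groups)
  for (p in pair_list) {
    shared_per_group[[p[1]]] <- shared_per_group[[p[1]]] + as.integer(p[3])
    shared_per_group[[p[2]]] <- shared_per_group[[p[2]]] + as.integer(p[3])
  }
  exclusive_n <- cfg$pool_sizes - shared_per_group
  if (any(exclusive_n < 0)) {
    stop("infeasible config: pairwise overlap demands exceed pool size for ",
         paste(groups[exclusive_n < 0], collapse = ", "), call. = FALSE)
  }
  total_alloc <- sum(vapply(pair_list, function(p) as.integer(p[3]), 0L)) +
    sum(exclusive_n)
  assert_that(total_alloc <= cfg$universe_size,
              "infeasible config: pool allocations exceed the universe size")

  perm <- sample(gene_ids)
  cursor <- 0L
  take <- function(n) {
    out <- perm[cursor + seq_len(n)]
    cursor <<- cursor + n
    out
  }
  pools <- setNames(lapply(groups, function(g) character()), groups)
  shared_blocks <- list()
  for (nm in names(pair_list)) {
    p <- pair_list[[nm]]
    blk <- take(as.integer(p[3]))
    shared_blocks[[nm]] <- blk
    pools[[p[1]]] <- c(pools[[p[1]]], blk)
    pools[[p[2]]] <- c(pools[[p[2]]], blk)
  }
  for (g in groups) pools[[g]] <- sort(c(pools[[g]], take(exclusive_n[[g]])))

  ## --- herbs, compounds, interactions --------------------------------------
  herb_ids <- character(); herb_groups <- character()
  for (g in groups) {
    ids <- sprintf("%s-H%02d", g, seq_len(cfg$herb_counts[[g]]))
    herb_ids <- c(herb_ids, ids)
    herb_groups <- c(herb_groups, rep(g, length(ids)))
  }
  herb_catalog <- data.frame(
    herb_id = herb_ids, group = herb_groups,
    local_name = sprintf("Synthetic herb %s", herb_ids),
    latin_name = sprintf("Herba synthetica %s", tolower(herb_ids)),
    stringsAsFactors = FALSE)

  compound_owner <- character()   # compound -> group (creation group)
  hc_rows <- list()
  next_comp <- 0L
  for (hi in seq_along(herb_ids)) {
    g <- herb_groups[hi]
    n_comp <- rpois_trunc1(1, cfg$compounds_per_herb)
    comps <- character(n_comp)
    for (ci in seq_len(n_comp)) {
      own_pool <- names(compound_owner)[compound_owner == g]
      if (length(own_pool) > 0 && stats::runif(1) < cfg$shared_compound_prob) {
        comps[ci] <- sample(own_pool, 1)
      } else {
        next_comp <- next_comp + 1L
        cid <- sprintf("C%04d", next_comp)
        compound_owner[cid] <- g
        comps[ci] <- cid
      }
    }
    hc_rows[[hi]] <- data.frame(herb_id = herb_ids[hi],
                                compound_id = unique(comps),
                                stringsAsFactors = FALSE)
  }
  herb_compound <- do.call(rbind, hc_rows)

  ct_rows <- list()
  for (cid in names(compound_owner)) {
    g <- compound_owner[[cid]]
    source_pool <- if (cfg$structure == "null") gene_ids else pools[[g]]
    mean_t <- if (stats::runif(1) < cfg$promiscuous_prob)
      cfg$promiscuous_mean else cfg$targets_per_compound
    n_t <- min(rpois_trunc1(1, mean_t),
               cfg$max_targets_per_compound, length(source_pool))
    genes <- sample(source_pool, n_t)
    ct_rows[[cid]] <- data.frame(compound_id = cid, target_gene = genes,
                                 score = draw_scores(n_t, cfg),
                                 stringsAsFactors = FALSE)
  }
  compound_target <- do.call(rbind, ct_rows)
  rownames(compound_target) <- NULL

  # Coverage pass (planted structure only): every pool gene gets at least one
  # interaction above the 700 threshold within its group.
  if (cfg$structure == "planted") {
    for (g in groups) {
      comps_g <- names(compound_owner)[compound_owner == g]
      covered <- unique(compound_target$target_gene[
        compound_target$compound_id %in% comps_g & compound_target$score > 700])
      missing <- setdiff(pools[[g]], covered)
      for (gene in missing) {
        have <- compound_target$compound_id %in% comps_g &
          compound_target$target_gene == gene
        if (any(have)) {
          compound_target$score[which(have)[1]] <- draw_scores(1, cfg, force_above = TRUE)
        } else {
          cid <- sample(comps_g, 1)
          compound_target <- rbind(compound_target, data.frame(
            compound_id = cid, target_gene = gene,
            score = draw_scores(1, cfg, force_above = TRUE),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  compound_target <- compound_target[order(compound_target$compound_id,
                                           compound_target$target_gene), ]
  rownames(compound_target) <- NULL

  ## --- annotation library ---------------------------------------------------
  fl_ids <- sprintf("FL%02d", seq_len(cfg$n_first_level))
  fl_names <- c("Cellular process", "Metabolic process", "Biological regulation",
                "Response to stimulus", "Localization", "Developmental process",
                "Immune system process", "Signaling", "Reproduction",
                "Biological adhesion")
  fl_names <- paste0(fl_names[((seq_len(cfg$n_first_level) - 1) %% length(fl_names)) + 1],
                     ifelse(seq_len(cfg$n_first_level) > length(fl_names), " (bis)", ""))
  home_group <- setNames(rep(NA_character_, cfg$universe_size), gene_ids)
  for (g in rev(groups)) home_group[pools[[g]]] <- g

  primary_cat <- character(cfg$universe_size)
  for (i in seq_len(cfg$universe_size)) {
    hg <- home_group[[gene_ids[i]]]
    skew <- if (!is.na(hg)) cfg$category_skew[[hg]] else NULL
    if (!is.null(skew) && stats::runif(1) < skew$prob) {
      primary_cat[i] <- skew$category
    } else {
      primary_cat[i] <- sample(fl_ids, 1)
    }
  }
  secondary <- stats::runif(cfg$universe_size) < cfg$multi_category_prob
  secondary_cat <- ifelse(secondary, sample(fl_ids, cfg$universe_size, replace = TRUE), NA)
  fl_members <- setNames(lapply(fl_ids, function(cid) {
    sort(gene_ids[primary_cat == cid |
                    (!is.na(secondary_cat) & secondary_cat == cid)])
  }), fl_ids)

  term_rows <- list()
  for (ci in seq_along(fl_ids)) {
    memb <- fl_members[[fl_ids[ci]]]
    for (ti in seq_len(cfg$terms_per_category)) {
      size <- min(max(5L, rpois_trunc1(1, cfg$term_size_mean)), length(memb))
      term_id <- sprintf("T%02d%02d", ci, ti)
      term_rows[[term_id]] <- list(
        name = sprintf("%s term %d", fl_names[ci], ti),
        genes = sort(sample(memb, size)))
    }
  }
  planted_term_id <- NA_character_
  planted_term_genes <- character()
  if (!is.null(cfg$planted_term) && cfg$planted_term$group %in% groups) {
    pg <- cfg$planted_term$group
    n_in <- round(cfg$planted_term$size * cfg$planted_term$effect)
    n_out <- cfg$planted_term$size - n_in
    outside <- setdiff(gene_ids, pools[[pg]])
    planted_term_genes <- sort(c(sample(pools[[pg]], min(n_in, length(pools[[pg]]))),
                                 sample(outside, n_out)))
    planted_term_id <- "TPLNT"
    term_rows[[planted_term_id]] <- list(
      name = sprintf("Planted process of %s", pg), genes = planted_term_genes)
  }

  ## --- diseases -------------------------------------------------------------
  chapters <- icd10_chapters()
  n_dis <- cfg$diseases_per_chapter * length(chapters)
  disease_ids <- sprintf("D%04d", seq_len(n_dis))
  disease_chapter <- rep(chapters, each = cfg$diseases_per_chapter)
  names(disease_chapter) <- disease_ids

  gda_genes <- sort(unique(c(unlist(pools, use.names = FALSE),
                             compound_target$target_gene)))
  gda_rows <- vector("list", length(gda_genes))
  sp <- cfg$chapter_skew_prob
  for (i in seq_along(gda_genes)) {
    gene <- gda_genes[i]
    hg <- home_group[[gene]]
    w <- rep(1, n_dis)
    if (!is.na(hg) && hg %in% names(cfg$chapter_skew)) {
      planted_ch <- cfg$chapter_skew[[hg]]
      in_ch <- disease_chapter == planted_ch
      if (any(in_ch) && sp < 1) {
        w[in_ch] <- (sp / (1 - sp)) * (sum(!in_ch) / sum(in_ch))
      }
    }
    n_d <- min(rpois_trunc1(1, cfg$diseases_per_gene), n_dis)
    ids <- sample(disease_ids, n_d, prob = w)
    gda_rows[[i]] <- data.frame(gene = gene, disease_id = ids,
                                disease_name = sprintf("Synthetic disease %s", ids),
                                score = round(stats::runif(n_d), 3),
                                stringsAsFactors = FALSE)
  }
  gda <- do.call(rbind, gda_rows)

  ## --- write files ----------------------------------------------------------
  paths <- c(
    herb_catalog = file.path(out_dir, "herb_catalog.tsv"),
    herb_compound = file.path(out_dir, "herb_compound.tsv"),
    compound_target = file.path(out_dir, "compound_target.tsv"),
    go_slim = file.path(out_dir, "go_slim.gmt"),
    first_level = file.path(out_dir, "first_level.gmt"),
    gda = file.path(out_dir, "gda.tsv"),
    icd_map = file.path(out_dir, "icd_map.tsv"),
    manifest = file.path(out_dir, "manifest.json"))

  write_tsv_plain(herb_catalog, paths[["herb_catalog"]])
  write_tsv_plain(herb_compound, paths[["herb_compound"]])
  ct_out <- compound_target
  ct_out$score <- format(ct_out$score, nsmall = 2, trim = TRUE)
  write_tsv_plain(ct_out, paths[["compound_target"]])
  writeLines(vapply(names(term_rows), function(tid) {
    paste(c(tid, term_rows[[tid]]$name, term_rows[[tid]]$genes), collapse = "\t")
  }, ""), paths[["go_slim"]])
  writeLines(vapply(seq_along(fl_ids), function(ci) {
    paste(c(fl_ids[ci], fl_names[ci], fl_members[[fl_ids[ci]]]), collapse = "\t")
  }, ""), paths[["first_level"]])
  gda_out <- gda
  gda_out$score <- format(gda_out$score, nsmall = 3, trim = TRUE)
  write_tsv_plain(gda_out, paths[["gda"]])
  write_tsv_plain(data.frame(disease_id = disease_ids,
                             chapter = unname(disease_chapter),
                             stringsAsFactors = FALSE), paths[["icd_map"]])

  manifest <- list(
    seed = seed,
    structure = cfg$structure,
    groups = groups,
    pools = pools,
    pool_sizes = as.list(cfg$pool_sizes),
    overlap = cfg$overlap,
    shared_blocks = shared_blocks,
    planted_term = list(id = planted_term_id,
                        group = if (!is.null(cfg$planted_term)) cfg$planted_term$group else NA,
                        genes = planted_term_genes),
    category_skew = cfg$category_skew,
    chapter_skew = as.list(cfg$chapter_skew),
    counts = list(herbs = nrow(herb_catalog),
                  compounds = length(compound_owner),
                  compound_target_edges = nrow(compound_target),
                  universe = cfg$universe_size,
                  diseases = n_dis))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")

  structure(list(paths = paths, manifest = manifest, out_dir = out_dir),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic analysis bundle in", x$out_dir, "\n")
  cat(sprintf("  %d herbs, %d compounds, %d compound-target edges, %d-gene universe\n",
              x$manifest$counts$herbs, x$manifest$counts$compounds,
              x$manifest$counts$compound_target_edges, x$manifest$counts$universe))
  invisible(x)
}
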