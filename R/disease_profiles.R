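#' Read a gene-disease association table
#'
#' TSV with columns \code{gene}, \code{disease_id}, \code{disease_name},
#' \code{score}; scores are curation-confidence values in [0, 1]
#' (DisGeNET-style). Duplicated (gene, disease_id) pairs are an error.
#'
#' @param path TSV file path.
#' @return data.frame with normalized gene symbols.
#' @export
read_gene_disease <- function(path) {
  df <- read_tsv_checked(path, c("gene", "disease_id", "disease_name", "score"))
  df$gene <- normalize_gene(df$gene)
  df$score <- suppressWarnings(as.numeric(df$score))
  assert_that(!anyNA(df$score), "malformed (non-numeric) score in gene-disease table")
  assert_that(all(df$score >= 0 & df$score <= 1), "gene-disease scores must lie in [0, 1]")
  key <- paste(df$gene, df$disease_id, sep = "\r")
  assert_that(!anyDuplicated(key), "duplicate (gene, disease_id) pair(s)")
  df
}

#' Read a disease-to-ICD-10-chapter map
#'
#' TSV with columns \code{disease_id}, \code{chapter}.
#'
#' @param path TSV file path.
#' @return named character vector disease_id -> chapter.
#' @export
read_icd_map <- function(path) {
  df <- read_tsv_checked(path, c("disease_id", "chapter"))
  assert_that(!anyDuplicated(df$disease_id), "duplicate disease_id in ICD map")
  setNames(df$chapter, df$disease_id)
}

#' Top-k scored diseases of one gene
#'
#' The \code{k} highest-scoring diseases among the gene's records; ties at
#' the score cutoff are broken by lexicographically ascending
#' \code{disease_id}, making the selection independent of input order. If
#' the gene has fewer than \code{k} diseases, all are returned.
#'
#' @param records data.frame with columns \code{disease_id}, \code{score}
#'   (rows for a single gene).
#' @param k number of diseases to keep (default 3).
#' @return character vector of disease ids, highest score first.
#' @export
top_k_diseases <- function(records, k = 3) {
  assert_that(k >= 1, "k must be at least 1")
  ord <- order(-records$score, records$disease_id)
  records$disease_id[ord][seq_len(min(k, nrow(records)))]
}

#' ICD-10 chapter frequency profiles per constitution type
#'
#' For each group, pools the top-\code{k} scored diseases of every target
#' gene in the group's set. By default a disease contributes one instance
#' per gene carrying it (frequency semantics); \code{unique_diseases = TRUE}
#' counts each disease once per group. Instances are mapped to ICD-10
#' chapters and normalized to proportions; diseases without a chapter
#' mapping are tallied as \code{unmapped} (with a warning) and excluded
#' from the proportions.
#'
#' @param collection a \code{target_sets} object.
#' @param records gene-disease data.frame (see
#'   \code{\link{read_gene_disease}}).
#' @param icd_map named character vector disease_id -> chapter.
#' @param k diseases per gene (default 3).
#' @param unique_diseases count each disease once per group instead of once
#'   per contributing gene.
#' @return named list of \code{disease_profile} objects (one per group):
#'   each has \code{group}, \code{proportions} (named by chapter, over all
#'   chapters seen in \code{icd_map}), \code{total} classified instances and
#'   \code{unmapped} count.
#' @export
disease_profile <- function(collection, records, icd_map, k = 3,
                            unique_diseases = FALSE) {
  assert_that(inherits(collection, "target_sets"), "`collection` must be target_sets")
  assert_that(k >= 1, "k must be at least 1")
  chapters <- sort(unique(unname(icd_map)))
  records$gene <- normalize_gene(records$gene)
  by_gene <- split(records[, c("disease_id", "score")], records$gene)
  top_by_gene <- lapply(by_gene, top_k_diseases, k = k)

  out <- list()
  total_unmapped <- 0L
  for (g in collection$groups) {
    genes <- intersect(collection$sets[[g]], names(top_by_gene))
    pooled <- unlist(top_by_gene[genes], use.names = FALSE)
    if (unique_diseases) pooled <- unique(pooled)
    mapped <- icd_map[pooled]
    unmapped <- sum(is.na(mapped))
    total_unmapped <- total_unmapped + unmapped
    mapped <- mapped[!is.na(mapped)]
    counts <- table(factor(mapped, levels = chapters))
    total <- sum(counts)
    proportions <- if (total > 0) as.numeric(counts) / total else as.numeric(counts)
    names(proportions) <- chapters
    out[[g]] <- structure(list(group = g, proportions = proportions,
                               total = total, unmapped = unmapped),
                          class = "disease_profile")
  }
  if (total_unmapped > 0) {
    warning(total_unmapped, " disease instance(s) had no ICD-10 chapter mapping")
  }
  out
}

#' @export
print.disease_profile <- function(x, ...) {
  cat(sprintf("Disease chapter profile for %s (%d instances, %d unmapped)\n",
              x$group, x$total, x$unmapped))
  top <- sort(x$proportions, decreasing = TRUE)
  for (nm in names(head(top[top > 0], 5))) {
    cat(sprintf("  %-55s %.3f\n", nm, top[[nm]]))
  }
  invisible(x)
}

#' The 22 standard ICD-10 chapter titles
#'
#' Convenience constant used by the synthetic-data generator; real analyses
#' supply the disease-to-chapter map as data.
#'
#' @return character vector of 22 chapter titles.
#' @export
icd10_chapters <- function() {
  c("Certain infectious and parasitic diseases",
    "Neoplasms",
    "Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism",
    "Endocrine, nutritional and metabolic diseases",
    "Mental, behavioural and neurodevelopmental disorders",
    "Diseases of the nervous system",
    "Diseases of the eye and adnexa",
    "Diseases of the ear and mastoid process",
    "Diseases of the circulatory system",
    "Diseases of the respiratory system",
    "Diseases of the digestive system",
    "Diseases of the skin and subcutaneous tissue",
    "Diseases of the musculoskeletal system and connective tissue",
    "Diseases of the genitourinary system",
    "Pregnancy, childbirth and the puerperium",
    "Certain conditions originating in the perinatal period",
    "Congenital malformations, deformations and chromosomal abnormalities",
    "Symptoms, signs and abnormal clinical and laboratory findings, not elsewhere classified",
    "Injury, poisoning and certain other consequences of external causes",
    "External causes of morbidity and mortality",
    "Factors influencing health status and contact with health services",
    "Codes for special purposes")
}
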