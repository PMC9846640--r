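#' Phylogenetic age classification of genes
#'
#' Each gene is assigned an age class from its best-hit protein identities
#' against a fixed hierarchy of outgroup proteomes, oldest first: a hit
#' (identity >= threshold) to Arabidopsis makes it Viridiplantae, otherwise
#' a hit to rice makes it Poaceae, otherwise a hit to maize makes it
#' Andropogoneae, and a gene with no qualifying hit is sorghum-specific.
#' Brachypodium hits may be present in the input; they are read but do not
#' enter the rule.
#'
#' @name gene-age
NULL

.AGE_CLASSES <- c("VIRIDIPLANTAE", "POACEAE", "ANDROPOGONEAE",
                  "SORGHUM_SPECIFIC")
.AGE_RULE <- c(arabidopsis = "VIRIDIPLANTAE", rice = "POACEAE",
               maize = "ANDROPOGONEAE")

#' Classify gene ages from best-hit identities
#'
#' @param hits data frame with columns `gene_id`, `species`, `identity`
#'   (fractional, in `[0, 1]`); one row per best hit. Species labels are
#'   matched case-insensitively against `arabidopsis`, `rice`, `maize`;
#'   other species (e.g. brachypodium) are ignored for classification.
#' @param gene_ids genes to classify; defaults to the genes occurring in
#'   `hits`. Genes listed here with no qualifying hit are sorghum-specific.
#' @param threshold minimum identity for a hit to count, in `(0, 1]`
#'   (default 0.5).
#' @return Data frame with columns `gene_id`, `age_class`.
#' @export
classify_gene_age <- function(hits, gene_ids = NULL, threshold = 0.5) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  need <- c("gene_id", "species", "identity")
  if (!is.data.frame(hits) || !all(need %in% names(hits)))
    stop("hits must be a data frame with columns gene_id, species, identity")
  if (nrow(hits) > 0L && (any(hits$identity < 0) || any(hits$identity > 1)))
    stop("identities must lie in [0, 1]")
  if (is.null(gene_ids)) gene_ids <- unique(hits$gene_id)
  species <- tolower(hits$species)
  cls <- rep("SORGHUM_SPECIFIC", length(gene_ids))
  # oldest clade wins: evaluate strictly in hierarchy order
  for (sp in rev(names(.AGE_RULE))) {
    ok <- hits$gene_id[species == sp & hits$identity >= threshold]
    cls[gene_ids %in% ok] <- .AGE_RULE[[sp]]
  }
  data.frame(gene_id = gene_ids, age_class = cls, stringsAsFactors = FALSE)
}

#' Age-class profile of a gene set
#'
#' @param classes data frame from [classify_gene_age()] (or any data frame
#'   with an `age_class` column).
#' @return Data frame with one row per age class (in order of antiquity):
#'   `count` summing to the number of genes and `fraction` summing to 1.
#' @export
age_profile <- function(classes) {
  if (!is.data.frame(classes) || !"age_class" %in% names(classes))
    stop("classes must be a data frame with an age_class column")
  if (nrow(classes) == 0L) stop("need at least one gene")
  bad <- setdiff(unique(classes$age_class), .AGE_CLASSES)
  if (length(bad) > 0L)
    stop("unknown age class: ", paste(bad, collapse = ", "))
  counts <- vapply(.AGE_CLASSES, function(k) sum(classes$age_class == k), 0L)
  data.frame(age_class = .AGE_CLASSES, count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(classes),
             row.names = NULL, stringsAsFactors = FALSE)
}
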