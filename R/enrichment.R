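#' GO-term enrichment and ideotype-group variant contrasts
#'
#' Genes hit by variants are tested per GO term with the classic one-sided
#' Fisher exact test (hypergeometric upper tail), keeping terms with raw
#' p < 0.05 (no multiple-testing correction enters the significance flag,
#' but a Benjamini-Hochberg column is emitted for reference). Group
#' contrasts select variants present in every in-group genotype and at most
#' `max_out` out-group genotypes (e.g. present in all three sweet genotypes
#' but absent from or rare among the non-sweet ones).
#'
#' @name enrichment-contrast
NULL

#' One-sided Fisher-exact GO enrichment
#'
#' For each term with annotated-gene count `K` in a population of size `N`,
#' and `k` of the `n` study genes annotated, the p-value is the
#' hypergeometric upper tail `P(X >= k)`. Results are sorted by ascending
#' p-value.
#'
#' @param study character vector of study gene ids (must be contained in the
#'   population).
#' @param annotation data frame with columns `gene_id`, `term_id` (one row
#'   per annotation).
#' @param population character vector of population (universe) gene ids;
#'   defaults to all genes in `annotation`.
#' @param alpha raw-p significance cutoff (default 0.05).
#' @return Data frame with columns `term`, `k`, `n_study`, `K`, `N`, `p`,
#'   `padj` (BH, reference only), `significant` (`p < alpha`).
#' @export
fisher_enrichment <- function(study, annotation, population = NULL,
                              alpha = 0.05) {
  need <- c("gene_id", "term_id")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation)))
    stop("annotation must be a data frame with columns gene_id, term_id")
  if (is.null(population)) population <- unique(annotation$gene_id)
  population <- unique(as.character(population))
  if (length(population) == 0L) stop("population is empty")
  bad <- setdiff(unique(annotation$gene_id), population)
  if (length(bad) > 0L)
    stop("annotated genes missing from population: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  study <- unique(as.character(study))
  off <- setdiff(study, population)
  if (length(off) > 0L)
    stop("study genes missing from population: ",
         paste(utils::head(off, 5L), collapse = ", "))
  N <- length(population)
  n <- length(study)
  term2genes <- split(annotation$gene_id, annotation$term_id)
  term2genes <- lapply(term2genes, unique)
  K <- lengths(term2genes)
  k <- vapply(term2genes, function(g) sum(study %in% g), 0L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(term2genes), k = as.integer(k),
                    n_study = n, K = as.integer(K), N = N, p = as.numeric(p),
                    stringsAsFactors = FALSE)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genomic span of variant identity keys
#'
#' Converts `chrom:pos:vtype:ref:alt` keys into 1-based closed intervals:
#' SNPs and insertions occupy the anchor position, deletions span the
#' deleted reference bases.
#'
#' @param keys character vector of variant keys (see [variant_key()]).
#' @return Data frame with columns `key`, `chrom`, `start`, `end`.
#' @export
variant_spans <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  if (any(lengths(parts) != 5L))
    stop("keys must have the form chrom:pos:vtype:ref:alt")
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- as.integer(vapply(parts, `[[`, "", 2L))
  vtype <- vapply(parts, `[[`, "", 3L)
  ref <- vapply(parts, `[[`, "", 4L)
  end <- pos
  del <- vtype == "DEL"
  end[del] <- pos[del] + nchar(ref[del]) - 1L
  data.frame(key = keys, chrom = chrom, start = pos, end = end,
             stringsAsFactors = FALSE)
}

#' Genes hit by variants
#'
#' A gene is reported when its 1-based closed interval intersects the span
#' of at least one variant (point position for SNPs/insertions, deleted
#' span for deletions).
#'
#' @param variants data frame with columns `chrom`, `start`, `end` (e.g.
#'   from [variant_spans()]), or a character vector of variant keys.
#' @param genes data frame with columns `chrom`, `start`, `end`, `id`.
#' @return Sorted character vector of unique gene ids.
#' @export
genes_hit_by_variants <- function(variants, genes) {
  if (is.character(variants)) variants <- variant_spans(variants)
  .check_intervals(genes, "genes")
  if (!all(c("chrom", "start", "end") %in% names(variants)))
    stop("variants must have columns chrom, start, end")
  if (nrow(variants) == 0L || nrow(genes) == 0L) return(character())
  hit <- unlist(lapply(intersect(unique(genes$chrom), unique(variants$chrom)),
                       function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    v <- variants[variants$chrom == ch, , drop = FALSE]
    gr <- IRanges::IRanges(start = g$start, end = g$end)
    vr <- IRanges::IRanges(start = v$start, end = v$end)
    g$id[IRanges::overlapsAny(gr, vr)]
  }))
  sort(unique(hit))
}

#' Select group-specific variants
#'
#' A variant is selected when it is present in every in-group genotype and
#' in at most `max_out` out-group genotypes. With `max_out = 0` this is
#' strict exclusivity; `max_out = 1` admits variants "rare among" the
#' out-group.
#'
#' @param table an [occupancy_table()].
#' @param in_group genotype labels that must all carry the variant.
#' @param out_group genotype labels against which rarity is assessed;
#'   defaults to all remaining genotypes in the table.
#' @param max_out maximum number of out-group genotypes allowed to carry the
#'   variant (default 1).
#' @return Sorted character vector of selected variant keys.
#' @export
group_specific_variants <- function(table, in_group, out_group = NULL,
                                    max_out = 1L) {
  stopifnot(inherits(table, "occupancy_table"))
  if (is.null(out_group)) out_group <- setdiff(colnames(table), in_group)
  unknown <- setdiff(c(in_group, out_group), colnames(table))
  if (length(unknown) > 0L)
    stop("unknown genotype label(s): ", paste(unknown, collapse = ", "))
  if (length(in_group) == 0L) stop("in_group must be nonempty")
  if (length(intersect(in_group, out_group)) > 0L)
    stop("in_group and out_group must be disjoint")
  if (max_out < 0L ||
      (length(out_group) > 0L && max_out > length(out_group)))
    stop("max_out must lie in [0, |out_group|]")
  in_all <- rowSums(table[, in_group, drop = FALSE]) == length(in_group)
  out_n <- if (length(out_group) == 0L) rep(0L, nrow(table)) else
    rowSums(table[, out_group, drop = FALSE])
  sort(rownames(table)[in_all & out_n <= max_out])
}
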