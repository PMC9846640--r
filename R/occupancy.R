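#' Pan-genome occupancy: core, shell and cloud classification
#'
#' After per-genotype normalization, variant sets are merged across genotypes
#' into a presence matrix (absence of a call means the genotype carries the
#' reference state). Each row is classified by how many of the N genotypes
#' carry it: core (all N), cloud (exactly one), shell (in between). The same
#' machinery applies to gene presence/absence tables from annotation
#' lift-over.
#'
#' @name pangenome-occupancy
NULL

#' Construct an occupancy table
#'
#' @param presence binary matrix (rows = variant keys or gene ids, columns =
#'   genotypes) with rownames and colnames set; every row must have at least
#'   one 1 (an entry absent everywhere never appears).
#' @param kind `"VARIANT"` or `"GENE"`.
#' @return An object of class `occupancy_table`: the presence matrix with a
#'   `kind` attribute.
#' @export
occupancy_table <- function(presence, kind = c("VARIANT", "GENE")) {
  kind <- match.arg(kind)
  presence <- as.matrix(presence)
  storage.mode(presence) <- "integer"
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence matrix needs row (entry) and column (genotype) names")
  if (anyDuplicated(colnames(presence)))
    stop("duplicate genotype labels")
  if (!all(presence %in% c(0L, 1L)))
    stop("presence matrix must be binary")
  if (nrow(presence) > 0L && any(rowSums(presence) == 0L))
    stop("entries absent from every genotype are not allowed")
  structure(presence, kind = kind, class = c("occupancy_table", "matrix"))
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("occupancy_table (%s): %d entries x %d genotypes\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  print(class_summary(x))
  invisible(x)
}

#' Merge per-genotype variant sets into an occupancy table
#'
#' One row per distinct identity key across all sets; presence is 1 where the
#' genotype carries the variant and 0 otherwise (absence = reference state,
#' the `-0` merge semantics). Inversions and translocations are excluded.
#'
#' @param sets list of two or more [variant_set()]s over the same reference
#'   coordinate space, with distinct genotype labels.
#' @return An [occupancy_table()] of kind `"VARIANT"`, rows ordered by key.
#' @export
merge_genotypes <- function(sets) {
  if (length(sets) < 2L) stop("need at least two variant sets")
  stopifnot(all(vapply(sets, inherits, TRUE, "variant_set")))
  genotypes <- vapply(sets, attr, "", "genotype")
  if (anyDuplicated(genotypes))
    stop("duplicate genotype labels: ",
         paste(unique(genotypes[duplicated(genotypes)]), collapse = ", "))
  keys_by_g <- lapply(sets, function(vs) {
    unique(variant_key(vs[vs$vtype %in% c("SNP", "INS", "DEL"), ,
                          drop = FALSE]))
  })
  all_keys <- sort(unique(unlist(keys_by_g)))
  presence <- vapply(keys_by_g, function(k) as.integer(all_keys %in% k),
                     integer(length(all_keys)))
  if (length(all_keys) == 1L) presence <- matrix(presence, nrow = 1L)
  dimnames(presence) <- list(all_keys, genotypes)
  occupancy_table(presence, kind = "VARIANT")
}

#' Genotype carrying an entry: re-projection
#'
#' Returns the entry keys present in one genotype column, recovering that
#' genotype's contribution to the merged table.
#'
#' @param table an [occupancy_table()].
#' @param genotype genotype label.
#' @return Character vector of keys, sorted.
#' @export
project_genotype <- function(table, genotype) {
  stopifnot(inherits(table, "occupancy_table"))
  if (!genotype %in% colnames(table))
    stop("unknown genotype: ", genotype)
  sort(rownames(table)[table[, genotype] == 1L])
}

#' Classify occupancy counts as core, shell or cloud
#'
#' Core: present in all N genotypes; cloud: unique to a single genotype;
#' shell: present in more than one but not all.
#'
#' @param count integer vector of presence counts, each in `[1, N]`.
#' @param N number of genotypes (>= 2).
#' @return Character vector over `CORE`, `SHELL`, `CLOUD`.
#' @examples
#' classify_occupancy(c(10, 1, 5), N = 10)
#' @export
classify_occupancy <- function(count, N) {
  if (length(N) != 1L || N < 2L) stop("N must be a single integer >= 2")
  count <- as.integer(count)
  if (any(is.na(count)) || any(count < 1L) || any(count > N))
    stop("counts must lie in [1, N]")
  out <- rep("SHELL", length(count))
  out[count == N] <- "CORE"
  out[count == 1L] <- "CLOUD"
  out
}

#' Occupancy spectrum
#'
#' Histogram of presence counts: for each k in 1..N, the number of entries
#' present in exactly k genotypes.
#'
#' @param table an [occupancy_table()].
#' @return Named integer vector of length N (names `"1"`..`"N"`), summing to
#'   the number of entries.
#' @export
occupancy_spectrum <- function(table) {
  stopifnot(inherits(table, "occupancy_table"))
  n <- ncol(table)
  counts <- tabulate(rowSums(table), nbins = n)
  names(counts) <- as.character(seq_len(n))
  counts
}

#' Per-class counts and percentages
#'
#' Summarizes an occupancy table (or pre-computed per-class counts) into the
#' core/shell/cloud layout used for pan-genome reporting: counts plus
#' percentages of the total, rounded to 2 decimals.
#'
#' @param x an [occupancy_table()], or a named numeric vector of counts with
#'   names among `CORE`, `SHELL`, `CLOUD` (so published count columns can be
#'   summarized directly).
#' @param ... unused.
#' @return Data frame with columns `class`, `count`, `percent`; counts sum to
#'   the total and percentages to 100 up to rounding.
#' @examples
#' class_summary(c(CORE = 22762, SHELL = 31218, CLOUD = 8064))
#' @export
class_summary <- function(x, ...) UseMethod("class_summary")

#' @rdname class_summary
#' @export
class_summary.occupancy_table <- function(x, ...) {
  if (nrow(x) == 0L) stop("empty occupancy table")
  cls <- classify_occupancy(rowSums(x), ncol(x))
  counts <- vapply(c("CORE", "SHELL", "CLOUD"), function(k) sum(cls == k), 0L)
  class_summary(counts)
}

#' @rdname class_summary
#' @export
class_summary.numeric <- function(x, ...) {
  if (is.null(names(x)) || !all(names(x) %in% c("CORE", "SHELL", "CLOUD")))
    stop("counts must be named with CORE/SHELL/CLOUD")
  full <- c(CORE = 0, SHELL = 0, CLOUD = 0)
  full[names(x)] <- x
  total <- sum(full)
  if (total <= 0) stop("total count must be positive")
  data.frame(class = names(full),
             count = as.numeric(full),
             percent = round(100 * as.numeric(full) / total, 2),
             row.names = NULL)
}

#' Genes whose flanked span overlaps a transposable element
#'
#' A gene is reported when its interval, extended by `flank` bp on both
#' sides, intersects at least one TE interval on the same chromosome.
#' Intervals are 1-based inclusive and boundary contact counts as overlap.
#'
#' @param genes,tes data frames with columns `chrom`, `start`, `end`, `id`.
#' @param flank non-negative flank width in bp (1000 for the shell-gene/TE
#'   screen).
#' @return Sorted character vector of unique gene ids overlapping >= 1 TE.
#' @export
flank_overlap <- function(genes, tes, flank = 1000L) {
  if (length(flank) != 1L || is.na(flank) || flank < 0)
    stop("flank must be a single non-negative integer")
  .check_intervals(genes, "genes")
  .check_intervals(tes, "tes")
  if (nrow(genes) == 0L || nrow(tes) == 0L) return(character())
  hit <- unlist(lapply(intersect(unique(genes$chrom), unique(tes$chrom)),
                       function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    t <- tes[tes$chrom == ch, , drop = FALSE]
    gr <- IRanges::IRanges(start = pmax(1L, g$start - as.integer(flank)),
                           end = g$end + as.integer(flank))
    tr <- IRanges::IRanges(start = t$start, end = t$end)
    g$id[IRanges::overlapsAny(gr, tr)]
  }))
  sort(unique(hit))
}

.check_intervals <- function(x, what) {
  need <- c("chrom", "start", "end", "id")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop(what, " must be a data frame with columns chrom, start, end, id")
  if (nrow(x) > 0L && any(x$start > x$end))
    stop(what, ": interval start > end")
  invisible(x)
}

#' Read a gene presence/absence TSV into an occupancy table
#'
#' Expects a tab-separated file with gene ids in the first column and one 0/1
#' column per genotype. Rows absent from every genotype are dropped with a
#' message (they carry no occupancy information).
#'
#' @param path TSV path.
#' @return An [occupancy_table()] of kind `"GENE"`.
#' @export
read_pav_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  empty <- rowSums(m) == 0L
  if (any(empty)) {
    message(sum(empty), " all-absent rows dropped")
    m <- m[!empty, , drop = FALSE]
  }
  occupancy_table(m, kind = "GENE")
}
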