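#' Presence/absence phylogeny
#'
#' Genotype relationships are inferred from binary presence/absence matrices
#' (gene PAVs, or SNP presence from the merged occupancy table): pairwise
#' Jaccard distances on the asymmetric binary encoding (joint absences carry
#' no information and are excluded), followed by Saitou-Nei neighbor joining.
#' Trees are `ape` \code{phylo} objects, so standard Newick I/O and tree
#' comparison tooling apply.
#'
#' @name pav-phylogeny
NULL

#' Jaccard distance between two binary vectors
#'
#' `d = (b01 + b10) / (b11 + b01 + b10)` where `bxy` counts coordinates with
#' pattern `(x, y)`; coordinates absent in both vectors are excluded
#' (asymmetric binary distance).
#'
#' @param a,b binary vectors of equal length, not both all-zero.
#' @return Distance in `[0, 1]`.
#' @examples
#' jaccard_distance(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 2/3
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  a <- as.integer(a); b <- as.integer(b)
  if (!all(c(a, b) %in% c(0L, 1L))) stop("vectors must be binary")
  union <- sum(a | b)
  if (union == 0L)
    stop("Jaccard distance undefined: both vectors are all-zero")
  sum(xor(a, b)) / union
}

#' Pairwise Jaccard distances between genotype columns
#'
#' @param m binary matrix (rows = features, columns = genotypes) or an
#'   [occupancy_table()].
#' @return A [stats::dist] object labelled by genotype.
#' @export
pav_distance_matrix <- function(m) {
  m <- unclass(as.matrix(m))
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("matrix must be binary")
  n11 <- crossprod(m)
  tot <- colSums(m)
  union <- outer(tot, tot, "+") - n11
  if (any(union == 0 & row(union) != col(union)))
    stop("Jaccard distance undefined for a pair of all-zero columns")
  d <- (union - n11) / union
  diag(d) <- 0
  stats::as.dist(d)
}

.check_distance_matrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(m < 0)) stop("distances must be non-negative")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is
#' joined, with branch lengths from the two-point formulas
#' `l_i = d(i,j)/2 + (r_i - r_j) / (2(n-2))`. Ties on Q are broken by the
#' lowest `(i, j)` pair in current label order, so the result is
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch, preserving the path length
#' between the joined leaves. NJ is exact on additive matrices: leaf-to-leaf
#' path lengths then reproduce the input distances.
#'
#' @param d a [stats::dist] object or symmetric distance matrix with labels
#'   (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  m <- .check_distance_matrix(d)
  n <- nrow(m)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  # active nodes carried as Newick subtree strings
  sub <- rownames(m)
  if (any(grepl("[,():;[:space:]]", sub)))
    stop("taxon labels must not contain Newick metacharacters")
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (n > 3L) {
    r <- rowSums(m)
    q <- (n - 2) * m - outer(r, r, "+")
    diag(q) <- Inf
    # first minimum scanning pairs (i < j) in current order
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (q[i, j] < bestq - 1e-12) { bestq <- q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- m[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- m[i, j] - li
    l <- clamp_pair(li, lj)
    new_sub <- sprintf("(%s:%.15g,%s:%.15g)", sub[i], l[1L], sub[j], l[2L])
    du <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    m2 <- rbind(cbind(m[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    sub <- c(sub[keep], new_sub)
    rownames(m2) <- colnames(m2) <- sprintf("n%d", seq_len(n - 1L))
    m <- m2
    n <- n - 1L
  }
  l1 <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
  l2 <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
  l3 <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 sub[1L], max(l1, 0), sub[2L], max(l2, 0), sub[3L], max(l3, 0))
  ape::read.tree(text = nwk)
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo` tree with at least one tip.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0L)
    stop("tree must be a non-empty 'phylo' object")
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  tree
}
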