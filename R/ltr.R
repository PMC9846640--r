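#' LTR retrotransposon insertion-age dating
#'
#' At insertion time the left and right long terminal repeats of an LTR
#' retrotransposon are identical; substitutions accumulate independently in
#' each copy afterwards, so their divergence dates the insertion. The two
#' LTRs are globally aligned, the Kimura two-parameter (K80) distance `K` is
#' computed from transition and transversion proportions, and the age is
#' `T = K / (2 r)` with `r` the substitution rate per site per million years
#' (default 0.013, the rice LTR molecular clock).
#'
#' @name ltr-dating
NULL

.DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Construct an LTR pair
#'
#' @param te_id element identifier.
#' @param left,right left and right LTR sequences (strings over A,C,G,T,N).
#' @return An object of class `ltr_pair`.
#' @export
ltr_pair <- function(te_id, left, right) {
  left <- toupper(left); right <- toupper(right)
  if (!nzchar(left) || !nzchar(right))
    stop("LTR sequences must be nonempty (te_id ", te_id, ")")
  if (!grepl("^[ACGTN]+$", left) || !grepl("^[ACGTN]+$", right))
    stop("LTR sequences must be over {A,C,G,T,N} (te_id ", te_id, ")")
  structure(list(te_id = as.character(te_id), left = left, right = right),
            class = "ltr_pair")
}

.encode_dna <- function(s) {
  code <- match(strsplit(s, "", fixed = TRUE)[[1L]],
                c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(code)) stop("sequence contains letters outside {A,C,G,T,N}")
  code
}

#' Globally align the two LTRs of a pair
#'
#' End-to-end optimal alignment under affine gap scoring (Gotoh
#' three-state dynamic programming, compiled): a gap of length L scores
#' `gap_open + L * gap_extend`; ambiguous bases (N) score 0 against
#' anything. The traceback is deterministic (fixed state precedence), so
#' repeated runs give identical alignments.
#'
#' @param pair an [ltr_pair()].
#' @param match,mismatch,gap_open,gap_extend alignment scores (defaults 2,
#'   -1, -5, -1).
#' @return List with equal-length gapped strings `left` and `right`, the
#'   alignment `score`, and `te_id`.
#' @export
align_ltr_pair <- function(pair, match = 2, mismatch = -1,
                           gap_open = -5, gap_extend = -1) {
  stopifnot(inherits(pair, "ltr_pair"))
  if (gap_open > 0 || gap_extend > 0 || mismatch > match)
    stop("gap penalties must be <= 0 and mismatch <= match")
  if (grepl("^N+$", pair$left) || grepl("^N+$", pair$right))
    stop("cannot align an all-N sequence (te_id ", pair$te_id, ")")
  aln <- .affine_align_cpp(.encode_dna(pair$left), .encode_dna(pair$right),
                           match, mismatch, gap_open, gap_extend)
  list(te_id = pair$te_id, left = aln$left, right = aln$right,
       score = aln$score)
}

#' Kimura two-parameter distance from an aligned pair
#'
#' Columns containing a gap or an N are excluded (pairwise deletion). Over
#' the remaining `L_used` columns, `P` is the proportion of transitions
#' (A<->G, C<->T) and `Q` of transversions; the distance is
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. When `1 - 2P - Q <= 0` or
#' `1 - 2Q <= 0` the pair is saturated and a condition of class
#' `pansorghum_saturation` is signalled, distinguishable from other errors.
#'
#' @param left,right equal-length aligned strings (gaps as `-`), or pass the
#'   list returned by [align_ltr_pair()] as `left`.
#' @return Object of class `k80_result`: list with `P`, `Q`, `K`, `L_used`.
#' @examples
#' k80_distance(strrep("A", 90), strrep("A", 90))$K  # 0
#' @export
k80_distance <- function(left, right = NULL) {
  if (is.list(left) && is.null(right)) {
    right <- left$right; left <- left$left
  }
  l <- strsplit(toupper(left), "", fixed = TRUE)[[1L]]
  r <- strsplit(toupper(right), "", fixed = TRUE)[[1L]]
  if (length(l) != length(r))
    stop("aligned sequences must have equal length")
  use <- l %in% c("A", "C", "G", "T") & r %in% c("A", "C", "G", "T")
  L <- sum(use)
  if (L == 0L) stop("no usable (gap- and N-free) columns")
  l <- l[use]; r <- r[use]
  diff <- l != r
  purine <- c("A", "G")
  transition <- diff & ((l %in% purine) == (r %in% purine))
  P <- sum(transition) / L
  Q <- sum(diff & !transition) / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    cond <- structure(
      class = c("pansorghum_saturation", "error", "condition"),
      list(message = sprintf(
        "saturated LTR divergence (P=%.3f, Q=%.3f): K80 distance undefined",
        P, Q), call = sys.call(-1)))
    stop(cond)
  }
  structure(list(P = P, Q = Q, K = -0.5 * log(w1) - 0.25 * log(w2),
                 L_used = L),
            class = "k80_result")
}

#' Insertion age from a K80 distance
#'
#' `T = K / (2 r)`, in million years.
#'
#' @param k a `k80_result` or a numeric K80 distance (substitutions/site).
#' @param rate substitution rate per site per million years (> 0); default
#'   0.013, the LTR molecular clock rate estimated in rice.
#' @param te_id optional element identifier carried through.
#' @return Object of class `age_estimate`: list with `te_id`, `K`, `rate`,
#'   `T_myr`.
#' @examples
#' estimate_age(0.026)$T_myr # 1 Myr
#' @export
estimate_age <- function(k, rate = 0.013, te_id = NA_character_) {
  if (length(rate) != 1L || is.na(rate) || rate <= 0)
    stop("rate must be a single positive number")
  K <- if (inherits(k, "k80_result")) k$K else as.numeric(k)
  if (is.na(K) || K < 0) stop("K must be a non-negative number")
  structure(list(te_id = te_id, K = K, rate = rate, T_myr = K / (2 * rate)),
            class = "age_estimate")
}

#' Extract LTR pairs from a genome
#'
#' Subsequences are taken 1-based inclusive at the left/right LTR
#' coordinates; minus-strand elements are reverse-complemented.
#'
#' @param genome a `Biostrings::DNAStringSet`, or path to a FASTA file.
#' @param coords data frame with columns `te_id`, `chrom`, `left_start`,
#'   `left_end`, `right_start`, `right_end` and optionally `strand`
#'   (`"+"`/`"-"`, default `"+"`).
#' @return List of [ltr_pair()] objects.
#' @export
extract_ltr_pairs <- function(genome, coords) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  need <- c("te_id", "chrom", "left_start", "left_end",
            "right_start", "right_end")
  if (!all(need %in% names(coords)))
    stop("coords must have columns ", paste(need, collapse = ", "))
  strand <- if ("strand" %in% names(coords)) coords$strand else
    rep("+", nrow(coords))
  lapply(seq_len(nrow(coords)), function(i) {
    ch <- coords$chrom[i]; id <- coords$te_id[i]
    if (!ch %in% names(genome))
      stop("unknown chromosome '", ch, "' for te_id ", id)
    len <- length(genome[[ch]])
    cut <- function(s, e) {
      if (is.na(s) || is.na(e) || s < 1L || e > len || s > e)
        stop("coordinates out of bounds for te_id ", id)
      x <- Biostrings::subseq(genome[[ch]], s, e)
      if (strand[i] == "-") x <- Biostrings::reverseComplement(x)
      as.character(x)
    }
    ltr_pair(id, cut(coords$left_start[i], coords$left_end[i]),
             cut(coords$right_start[i], coords$right_end[i]))
  })
}

#' Read pre-extracted LTR pairs from a paired FASTA
#'
#' Sequence names must follow `<te_id>/L` and `<te_id>/R`.
#'
#' @param path FASTA path.
#' @return List of [ltr_pair()] objects, one per complete pair.
#' @export
read_ltr_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  side <- sub("^.*/", "", nm)
  id <- sub("/[LR]$", "", nm)
  if (!all(side %in% c("L", "R")))
    stop("sequence names must end in /L or /R")
  ids <- unique(id)
  lapply(ids, function(i) {
    l <- which(id == i & side == "L"); r <- which(id == i & side == "R")
    if (length(l) != 1L || length(r) != 1L)
      stop("te_id ", i, " does not have exactly one /L and one /R sequence")
    ltr_pair(i, as.character(seqs[[l]]), as.character(seqs[[r]]))
  })
}

#' Write LTR pairs as a paired FASTA
#'
#' @param pairs list of [ltr_pair()] objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_ltr_fasta <- function(pairs, path) {
  seqs <- unlist(lapply(pairs, function(p) {
    stats::setNames(c(p$left, p$right), paste0(p$te_id, c("/L", "/R")))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Per-element LTR age table
#'
#' Runs the full dating pipeline (align, K80 distance, `T = K/(2r)`) for a
#' list of LTR pairs. Saturated pairs are kept with `NA` distance/age and
#' `saturated = TRUE` rather than dropped; the number flagged is reported as
#' an attribute.
#'
#' @param pairs list of [ltr_pair()] objects.
#' @param rate substitution rate per site per Myr (default 0.013).
#' @param ... alignment scores passed to [align_ltr_pair()].
#' @return Data frame with columns `te_id`, `P`, `Q`, `K`, `T_myr`,
#'   `L_used`, `saturated`; attribute `n_saturated`.
#' @export
ltr_age_table <- function(pairs, rate = 0.013, ...) {
  rows <- lapply(pairs, function(p) {
    aln <- align_ltr_pair(p, ...)
    k <- tryCatch(k80_distance(aln), pansorghum_saturation = function(e) NULL)
    if (is.null(k))
      return(data.frame(te_id = p$te_id, P = NA_real_, Q = NA_real_,
                        K = NA_real_, T_myr = NA_real_, L_used = NA_integer_,
                        saturated = TRUE))
    data.frame(te_id = p$te_id, P = k$P, Q = k$Q, K = k$K,
               T_myr = estimate_age(k, rate)$T_myr, L_used = k$L_used,
               saturated = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_saturated") <- sum(out$saturated)
  out
}
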