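#' Synthetic data with ground truth
#'
#' Generators for every input the pipeline consumes: syntenic-caller VCFs
#' with injected duplicates and fragmented insertions, per-genotype variant
#' sets with a planned core/shell/cloud occupancy structure, presence/absence
#' matrices evolved by irreversible gene loss on a known tree, LTR pairs
#' diverged under a K80 process of known age, and GO annotations with
#' planted enriched terms. Each generator is a pure function of its
#' parameters and `seed` (one explicit random stream per invocation, global
#' RNG state restored afterwards) and returns a `truth` list sufficient to
#' score every downstream operation.
#'
#' @name synthetic-data
NULL

.with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.PANEL_GENOTYPES <- c("Grassl", "PI329311", "PI506069", "PI510757",
                      "ChineseAmber", "Rio", "Leoti", "PI229841",
                      "PI297155", "PI655972")

#' Default genotype labels for a panel of a given size
#'
#' For a 10-genotype panel the CP-NAM parent names are used (three sweet:
#' ChineseAmber, Rio, Leoti); otherwise generic labels `g01`, `g02`, ...
#'
#' @param n panel size.
#' @return Character vector of length `n`.
#' @export
panel_genotypes <- function(n) {
  if (n == length(.PANEL_GENOTYPES)) .PANEL_GENOTYPES
  else sprintf("g%02d", seq_len(n))
}

#' Simulate a syntenic-caller VCF with injected artefacts
#'
#' Writes a VCF in the caller's dialect (INFO keys `ChrB`, `Parent`,
#' `DupType`; `END` for inversion/translocation spans) containing
#' `n_variants` distinct variants, a fraction of the insertions split into
#' 2-4 fragment records sharing one anchor position, and
#' `round(dup_rate * n_variants)` byte-identical duplicate lines. Body lines
#' are written in shuffled order. The truth list records exactly what
#' normalization must undo.
#'
#' @param n_variants number of distinct variants (> 0).
#' @param type_mix named sampling weights over SNP/INS/DEL/INV/TRANS.
#' @param dup_rate,frag_rate duplicate-injection and insertion-fragmentation
#'   rates in `[0, 1]`.
#' @param n_chrom number of chromosomes (`Chr01`...).
#' @param seed integer seed.
#' @param path output VCF path (default: a tempfile).
#' @return List with `path`, `genotype`, and `truth` (fields
#'   `duplicates`, `fragment_clusters`, `extra_fragment_records`,
#'   `written_records`, `written_type_counts`, `normalized_type_counts`,
#'   `total_insert_len`).
#' @export
simulate_syri_vcf <- function(n_variants = 500,
                              type_mix = c(SNP = 0.6, INS = 0.15, DEL = 0.15,
                                           INV = 0.05, TRANS = 0.05),
                              dup_rate = 0.05, frag_rate = 0.1,
                              n_chrom = 10, seed = 1,
                              path = tempfile(fileext = ".vcf")) {
  if (n_variants <= 0) stop("n_variants must be positive")
  if (dup_rate < 0 || dup_rate > 1 || frag_rate < 0 || frag_rate > 1)
    stop("rates must lie in [0, 1]")
  stopifnot(all(names(type_mix) %in% .VTYPES))
  .with_seed(seed, {
    chroms <- sprintf("Chr%02d", seq_len(n_chrom))
    chrom <- sample(chroms, n_variants, replace = TRUE)
    pos <- integer(n_variants)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(500000L, length(idx)))
    }
    vtype <- sample(names(type_mix), n_variants, replace = TRUE,
                    prob = type_mix)
    base <- c("A", "C", "G", "T")
    ref <- character(n_variants); alt <- character(n_variants)
    info_extra <- character(n_variants)
    insert_len <- integer(n_variants)
    for (i in seq_len(n_variants)) {
      anchor <- sample(base, 1L)
      switch(vtype[i],
        SNP = { ref[i] <- anchor
                alt[i] <- sample(setdiff(base, anchor), 1L) },
        INS = { insert_len[i] <- sample(1:120, 1L)
                ref[i] <- anchor
                alt[i] <- paste0(anchor, .rand_dna(insert_len[i])) },
        DEL = { ref[i] <- paste0(anchor, .rand_dna(sample(1:120, 1L)))
                alt[i] <- anchor },
        { ref[i] <- anchor
          alt[i] <- sprintf("<%s>", vtype[i])
          info_extra[i] <- sprintf(";END=%d", pos[i] + sample(100:10000, 1L)) })
    }
    info <- sprintf("ChrB=%s;Parent=SYN%d%s", chrom, seq_len(n_variants),
                    info_extra)
    lines <- paste(chrom, pos, sprintf("VAR%05d", seq_len(n_variants)),
                   ref, alt, ".", "PASS", info, sep = "\t")
    line_type <- vtype

    # fragment a subset of multi-base insertions into >= 2 records at the
    # same anchor; pieces must be pairwise distinct so they survive dedup
    frag_candidates <- which(vtype == "INS" & insert_len >= 2L)
    fragged <- frag_candidates[stats::runif(length(frag_candidates)) <
                                 frag_rate]
    n_extra <- 0L
    for (i in fragged) {
      ins <- substring(alt[i], 2L)
      len <- nchar(ins)
      pieces <- NULL
      for (try in 1:20) {
        nf <- sample(2:min(4L, len), 1L)
        cuts <- sort(sample.int(len - 1L, nf - 1L))
        cand <- substring(ins, c(1L, cuts + 1L), c(cuts, len))
        if (!anyDuplicated(cand)) { pieces <- cand; break }
      }
      if (is.null(pieces)) { fragged <- setdiff(fragged, i); next }
      frag_lines <- paste(chrom[i], pos[i],
                          sprintf("VAR%05d.%d", i, seq_along(pieces)),
                          ref[i], paste0(ref[i], pieces), ".", "PASS",
                          sprintf("%s;DupType=fragment", info[i]), sep = "\t")
      lines[i] <- frag_lines[1L]
      lines <- c(lines, frag_lines[-1L])
      line_type <- c(line_type, rep("INS", length(pieces) - 1L))
      n_extra <- n_extra + length(pieces) - 1L
    }

    n_dup <- as.integer(round(dup_rate * n_variants))
    if (n_dup > 0L) {
      dup_idx <- sample(seq_along(lines), n_dup, replace = TRUE)
      lines <- c(lines, lines[dup_idx])
      line_type <- c(line_type, line_type[dup_idx])
    }
    ord <- sample(seq_along(lines))
    lines <- lines[ord]; line_type <- line_type[ord]

    header <- c("##fileformat=VCFv4.2", "##source=syntenic-caller-simulator",
                sprintf("##contig=<ID=%s>", chroms),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    writeLines(c(header, lines), path)

    truth <- list(
      seed = seed,
      n_variants = n_variants,
      duplicates = n_dup,
      fragment_clusters = length(fragged),
      extra_fragment_records = n_extra,
      written_records = length(lines),
      written_type_counts = as.list(table(factor(line_type,
                                                 levels = .VTYPES))),
      normalized_type_counts = as.list(table(factor(vtype,
                                                    levels = .VTYPES))),
      total_insert_len = sum(insert_len))
    list(path = path, genotype = "simulated", truth = truth)
  })
}

#' Simulate per-genotype variant sets with planned occupancy
#'
#' Creates `n_core + n_shell + n_cloud` distinct SNP identities and assigns
#' each to carriers so that the merged occupancy table classifies exactly
#' the requested number of entries into each class. Shell occupancy levels
#' are drawn from `shell_spectrum`; the default mirrors the empirical shape
#' of crop pan-genomes (mode at N-1 genomes, secondary mode at 2).
#'
#' @param n_genotypes panel size N (>= 2).
#' @param n_core,n_shell,n_cloud class counts (not all zero).
#' @param seed integer seed.
#' @param shell_spectrum optional weights for occupancy levels `2..N-1`.
#' @return List with `sets` (per-genotype [variant_set()]s), `table` (the
#'   planned [occupancy_table()]), and `truth` (`class_counts`, `spectrum`).
#' @export
simulate_occupancy <- function(n_genotypes = 10, n_core = 62,
                               n_shell = 8556, n_cloud = 16087, seed = 1,
                               shell_spectrum = NULL) {
  if (n_genotypes < 2L) stop("need at least two genotypes")
  if (any(c(n_core, n_shell, n_cloud) < 0) ||
      n_core + n_shell + n_cloud == 0L)
    stop("class counts must be non-negative and not all zero")
  if (n_shell > 0L && n_genotypes < 3L)
    stop("shell entries need N >= 3")
  N <- n_genotypes
  genotypes <- panel_genotypes(N)
  .with_seed(seed, {
    total <- n_core + n_shell + n_cloud
    chrom <- sprintf("Chr%02d", sample.int(10L, total, replace = TRUE))
    pos <- integer(total)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(5000000L, length(idx)))
    }
    base <- c("A", "C", "G", "T")
    ref <- sample(base, total, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(base, b), 1L), "")
    counts <- integer(total)
    counts[seq_len(n_core)] <- N
    if (n_shell > 0L) {
      levels_shell <- 2:(N - 1)
      w <- if (is.null(shell_spectrum)) {
        w0 <- rep(1, length(levels_shell))
        w0[length(w0)] <- 6   # mode at N-1 of N
        w0[1L] <- 3           # secondary mode at 2 of N
        w0
      } else rep_len(shell_spectrum, length(levels_shell))
      counts[n_core + seq_len(n_shell)] <-
        sample(levels_shell, n_shell, replace = TRUE, prob = w)
    }
    counts[n_core + n_shell + seq_len(n_cloud)] <- 1L
    presence <- matrix(0L, total, N,
                       dimnames = list(paste(chrom, pos, "SNP", ref, alt,
                                             sep = ":"), genotypes))
    for (i in seq_len(total))
      presence[i, sample.int(N, counts[i])] <- 1L
    ord <- order(rownames(presence))
    presence <- presence[ord, , drop = FALSE]
    table <- occupancy_table(presence, kind = "VARIANT")
    chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
    sets <- lapply(genotypes, function(g) {
      carry <- presence[, g] == 1L
      variant_set(data.frame(chrom = chrom[carry], pos = pos[carry],
                             ref = ref[carry], alt = alt[carry],
                             vtype = "SNP", stringsAsFactors = FALSE),
                  genotype = g, provenance = "simulate_occupancy")
    })
    names(sets) <- genotypes
    truth <- list(seed = seed,
                  class_counts = c(CORE = n_core, SHELL = n_shell,
                                   CLOUD = n_cloud),
                  spectrum = stats::setNames(tabulate(counts, nbins = N),
                                             as.character(seq_len(N))))
    list(sets = sets, table = table, truth = truth)
  })
}

#' Simulate gene presence/absence by irreversible loss on a tree
#'
#' Every gene is present at the root; along each branch of length `b` it is
#' lost with probability `1 - exp(-loss_rate * b)` and, once lost, stays
#' lost in all descendants. Genes lost in every tip carry no signal and are
#' redrawn (documented limit: as `loss_rate` approaches 0 the matrix is
#' all-ones).
#'
#' @param tree an `ape::phylo` tree or a Newick string.
#' @param n_genes number of genes.
#' @param loss_rate loss rate per unit branch length, in `(0, 1)`.
#' @param seed integer seed.
#' @return List with `pav` (binary matrix genes x tips) and `truth`
#'   (`tree`, `newick`).
#' @export
simulate_pav_on_tree <- function(tree, n_genes = 2000, loss_rate = 0.25,
                                 seed = 1) {
  if (is.character(tree)) {
    tree <- tryCatch(ape::read.tree(text = tree), error = function(e) NULL,
                     warning = function(w) NULL)
    if (is.null(tree)) stop("malformed Newick string")
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (length(loss_rate) != 1L || loss_rate <= 0 || loss_rate >= 1)
    stop("loss_rate must lie in (0, 1)")
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1L
  p_loss <- 1 - exp(-loss_rate * tree$edge.length)
  .with_seed(seed, {
    sim <- function(ng) {
      state <- matrix(1L, ng, n_tip + n_node)
      for (e in seq_len(nrow(tree$edge))) {
        parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
        survive <- stats::rbinom(ng, 1L, 1 - p_loss[e])
        state[, child] <- state[, parent] * survive
      }
      state[, seq_len(n_tip), drop = FALSE]
    }
    pav <- sim(n_genes)
    for (iter in 1:100) {
      empty <- rowSums(pav) == 0L
      if (!any(empty)) break
      pav[empty, ] <- sim(sum(empty))
    }
    if (any(rowSums(pav) == 0L))
      stop("loss_rate too high: could not generate informative genes")
    dimnames(pav) <- list(sprintf("gene%05d", seq_len(n_genes)),
                          tree$tip.label)
    list(pav = pav,
         truth = list(seed = seed, tree = tree,
                      newick = ape::write.tree(tree)))
  })
}

#' Simulate LTR pairs of known insertion age
#'
#' Each element descends from a random ancestral LTR of the given length;
#' the left and right copies evolve independently for `true_t_myr` million
#' years under a K80 process with rate `rate` substitutions/site/Myr and
#' transition/transversion rate ratio `kappa`, using the exact K80 site
#' transition probabilities at branch distance `rate * true_t_myr`. The
#' expected pairwise divergence is `2 * rate * true_t_myr`
#' substitutions/site.
#'
#' @param n number of pairs.
#' @param true_t_myr true insertion age in Myr (>= 0).
#' @param rate substitution rate per site per Myr.
#' @param kappa transition/transversion rate ratio (kappa = 2 resembles
#'   plant LTR data; kappa < 1 is transversion-rich).
#' @param length LTR length in bp.
#' @param seed integer seed.
#' @return List with `pairs` (list of [ltr_pair()]) and `truth`
#'   (`true_t_myr`, `expected_K`, `rate`, `kappa`).
#' @export
simulate_ltr_pairs <- function(n = 100, true_t_myr = 1, rate = 0.013,
                               kappa = 2, length = 5000, seed = 1) {
  if (n <= 0 || length <= 0 || rate <= 0 || kappa <= 0 || true_t_myr < 0)
    stop("n, length, rate, kappa must be positive and true_t_myr >= 0")
  d <- rate * true_t_myr
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  p_same <- 0.25 + 0.25 * exp(-4 * beta * d) +
    0.5 * exp(-2 * (alpha + beta) * d)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) -
    0.5 * exp(-2 * (alpha + beta) * d)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * d)  # each of the two targets
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", C = "T", G = "A", T = "C")
  tv1 <- c(A = "C", C = "A", G = "C", T = "A")
  tv2 <- c(A = "T", C = "G", G = "T", T = "G")
  evolve <- function(anc) {
    u <- stats::runif(base::length(anc))
    out <- anc
    sel <- u >= p_same & u < p_same + p_ts
    out[sel] <- ts_partner[anc[sel]]
    sel <- u >= p_same + p_ts & u < p_same + p_ts + p_tv
    out[sel] <- tv1[anc[sel]]
    sel <- u >= p_same + p_ts + p_tv
    out[sel] <- tv2[anc[sel]]
    out
  }
  .with_seed(seed, {
    pairs <- lapply(seq_len(n), function(i) {
      anc <- sample(bases, length, replace = TRUE)
      ltr_pair(sprintf("TE%04d", i),
               paste(evolve(anc), collapse = ""),
               paste(evolve(anc), collapse = ""))
    })
    list(pairs = pairs,
         truth = list(seed = seed, true_t_myr = true_t_myr,
                      expected_K = 2 * d, rate = rate, kappa = kappa))
  })
}

#' Simulate a GO annotation with planted enriched terms
#'
#' Builds a gene population annotated with `n_terms` terms of
#' `term_size` genes each, then draws a study set in which genes annotated
#' to the planted terms are over-sampled by the stated `fold`; `fold = 1`
#' is the null scenario.
#'
#' @param n_pop population size.
#' @param n_terms number of GO terms.
#' @param planted_terms number of planted terms, or a character vector of
#'   term ids (must be a subset of the generated terms).
#' @param fold over-sampling factor for planted-term genes (>= 1).
#' @param n_study study-set size (<= `n_pop`).
#' @param term_size genes per term.
#' @param seed integer seed.
#' @return List with `annotation` (data frame `gene_id`, `term_id`),
#'   `study`, `population`, and `truth` (`planted`, `fold`).
#' @export
simulate_enrichment <- function(n_pop = 2000, n_terms = 50,
                                planted_terms = 3, fold = 8, n_study = 100,
                                term_size = 40, seed = 1) {
  if (n_study > n_pop) stop("n_study must not exceed n_pop")
  if (fold < 1) stop("fold must be >= 1")
  if (term_size > n_pop) stop("term_size must not exceed n_pop")
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  planted <- if (is.numeric(planted_terms)) {
    if (planted_terms > n_terms) stop("more planted terms than terms")
    terms[seq_len(planted_terms)]
  } else {
    if (!all(planted_terms %in% terms))
      stop("planted_terms must be a subset of the generated terms")
    planted_terms
  }
  .with_seed(seed, {
    population <- sprintf("gene%05d", seq_len(n_pop))
    annotation <- do.call(rbind, lapply(terms, function(tm) {
      data.frame(gene_id = sample(population, term_size),
                 term_id = tm, stringsAsFactors = FALSE)
    }))
    planted_genes <- unique(annotation$gene_id[annotation$term_id %in%
                                                 planted])
    w <- ifelse(population %in% planted_genes, fold, 1)
    study <- sample(population, n_study, prob = w)
    list(annotation = annotation, study = study, population = population,
         truth = list(seed = seed, planted = planted, fold = fold))
  })
}
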