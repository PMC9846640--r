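# Shared fixtures and independent oracles.

write_vcf_fixture <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               body), path)
  path
}

# 2 SNPs, 2 DELs, 1 INS
toy_vcf_body <- c(
  "Chr01\t100\tv1\tA\tG\t.\tPASS\tChrB=Chr01;Parent=SYN1",
  "Chr01\t200\tv2\tC\tT\t.\tPASS\t.",
  "Chr02\t300\tv3\tATTT\tA\t.\tPASS\tDupType=copy",
  "Chr02\t400\tv4\tGCC\tG\t.\tPASS\t.",
  "Chr02\t500\tv5\tA\tACGT\t.\tPASS\t.")

toy_variant_set <- function(genotype = "toy") {
  suppressWarnings(read_syri_vcf(write_vcf_fixture(toy_vcf_body), genotype))
}

random_intervals <- function(n, chroms = sprintf("Chr%02d", 1:3),
                             max_pos = 50000L, max_len = 3000L,
                             prefix = "iv") {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE) - 1L,
             id = sprintf("%s%04d", prefix, seq_len(n)),
             stringsAsFactors = FALSE)
}

# all-pairs interval overlap, independent of IRanges
brute_flank_overlap <- function(genes, tes, flank) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    any(tes$chrom == g$chrom &
          tes$start <= g$end + flank &
          tes$end >= g$start - flank)
  }, logical(1))
  sort(unique(genes$id[hit]))
}

# hypergeometric upper tail from first principles (choose() ratios only)
hyper_upper_oracle <- function(k, K, n, N) {
  j <- max(0L, n + K - N):min(n, K)
  terms <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  sum(terms[j >= k])
}

# independent pure-R Gotoh DP, scores only (gap of length L: open + L*ext)
r_align_score <- function(s1, s2, match = 2, mismatch = -1,
                          open = -5, ext = -1) {
  x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]
  n <- length(x); m <- length(y); NEG <- -1e30
  sub <- function(a, b) if (a == "N" || b == "N") 0 else
    if (a == b) match else mismatch
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- open + ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- open + ext * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub(x[i], y[j])
    X[i + 1, j + 1] <- max(M[i, j + 1] + open + ext, X[i, j + 1] + ext,
                           Y[i, j + 1] + open + ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + open + ext, X[i + 1, j] + open + ext,
                           Y[i + 1, j] + ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# fixed 10-leaf reference topology used in recovery experiments
balanced10_newick <- function() {
  paste0("((A:0.4,B:0.4):0.3,(C:0.4,D:0.4):0.3,((E:0.4,F:0.4):0.3,",
         "((G:0.4,H:0.4):0.3,(I:0.4,J:0.4):0.3):0.3):0.3);")
}

rand_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# deterministic best-hit table with known class fractions
make_age_hits <- function(n_genes, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-12)
  cls <- rep(names(fractions), round(fractions * n_genes))
  cls <- cls[seq_len(n_genes)]
  genes <- sprintf("g%05d", seq_len(n_genes))
  rows <- list(
    VIRIDIPLANTAE = c("arabidopsis", "rice", "maize"),
    POACEAE = c("rice", "maize"),
    ANDROPOGONEAE = "maize",
    SORGHUM_SPECIFIC = character())
  hits <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    sp <- rows[[cls[i]]]
    if (length(sp) == 0) return(NULL)
    data.frame(gene_id = genes[i], species = sp, identity = 0.8,
               stringsAsFactors = FALSE)
  }))
  list(hits = hits, gene_ids = genes,
       truth = table(factor(cls, levels = names(rows))) / n_genes)
}
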