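test_that("identical LTRs align without gaps or mismatches", {
  s <- "ACGTACGTACGTACGT"
  a <- align_ltr_pair(ltr_pair("t", s, s))
  expect_equal(a$left, s)
  expect_equal(a$right, s)
  expect_equal(a$score, 2 * nchar(s))
})

test_that("a single substitution aligns as one mismatch column", {
  a <- align_ltr_pair(ltr_pair("t", "ACGT", "AGGT"))
  expect_equal(a$left, "ACGT")
  expect_equal(a$right, "AGGT")
  expect_equal(a$score, 3 * 2 - 1)
  expect_equal(a$score, r_align_score("ACGT", "AGGT"))
})

test_that("alignment scores equal two independent oracles on random pairs", {
  withr::with_seed(37, {
    for (rep in 1:8) {
      s1 <- rand_seq(50)
      s2 <- rand_seq(sample(40:60, 1))
      a <- align_ltr_pair(ltr_pair("t", s1, s2))
      expect_equal(a$score, r_align_score(s1, s2))
      submat <- matrix(-1, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                                 c("A","C","G","T","N")))
      diag(submat) <- 2; submat["N", ] <- 0; submat[, "N"] <- 0
      ref <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                           substitutionMatrix = submat,
                                           gapOpening = 5, gapExtension = 1)
      expect_equal(a$score, Biostrings::score(ref))
      # aligned strings reproduce the score
      cols_l <- strsplit(a$left, "")[[1]]; cols_r <- strsplit(a$right, "")[[1]]
      expect_equal(nchar(a$left), nchar(a$right))
    }
  })
  expect_error(align_ltr_pair(ltr_pair("t", "NNNN", "ACGT")), "all-N")
})

test_that("K80 distances follow the closed form and exclude gap/N columns", {
  same <- k80_distance(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_equal(same$P, 0); expect_equal(same$Q, 0); expect_equal(same$K, 0)

  # L=100 with 10 transitions: P=0.1, Q=0, K = -1/2 log(0.8)
  l <- strrep("A", 100)
  r <- paste0(strrep("G", 10), strrep("A", 90))
  k <- k80_distance(l, r)
  expect_equal(k$P, 0.1)
  expect_equal(k$Q, 0)
  expect_equal(k$K, -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(k$L_used, 100L)

  # gap and N columns drop from the denominator
  k2 <- k80_distance("AC-GN", "ACCGT")
  expect_equal(k2$L_used, 3L)

  expect_error(k80_distance("----", "ACGT"), "usable")
})

test_that("saturated pairs raise a distinct condition", {
  # P=0.3, Q=0.45 -> 1-2P-Q < 0
  l <- paste0(strrep("A", 100))
  r <- paste0(strrep("G", 30), strrep("C", 45), strrep("A", 25))
  expect_error(k80_distance(l, r), class = "pansorghum_saturation")
  expect_error(k80_distance(strrep("A", 10), strrep("C", 10)),
               class = "pansorghum_saturation")
})

test_that("K80 reduces to Jukes-Cantor at the 1:2 transition:transversion ratio", {
  # 5 transitions + 10 transversions over L=300
  l <- strrep("A", 300)
  r <- paste0(strrep("G", 5), strrep("C", 5), strrep("T", 5), strrep("A", 285))
  k <- k80_distance(l, r)
  p <- 15 / 300
  expect_equal(k$K, -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
})

test_that("K80 distance agrees with the reference implementation", {
  withr::with_seed(67, {
    for (rep in 1:5) {
      sim <- simulate_ltr_pairs(n = 1, true_t_myr = 2, length = 500,
                                seed = 67 + rep)
      p <- sim$pairs[[1]]
      k <- k80_distance(p$left, p$right)
      bin <- ape::as.DNAbin(rbind(strsplit(p$left, "")[[1]],
                                  strsplit(p$right, "")[[1]]))
      expect_equal(k$K, as.numeric(ape::dist.dna(bin, model = "K80")),
                   tolerance = 1e-9)
    }
  })
})

test_that("ages follow T = K/(2r) and scale linearly in K", {
  expect_equal(estimate_age(0)$T_myr, 0)
  expect_equal(estimate_age(0.026, rate = 0.013)$T_myr, 1)
  expect_equal(estimate_age(0.111572, rate = 0.013)$T_myr, 4.291,
               tolerance = 1e-4)
  expect_equal(estimate_age(3 * 0.02)$T_myr, 3 * estimate_age(0.02)$T_myr)
  expect_equal(estimate_age(0.02, rate = 0.026)$T_myr,
               0.5 * estimate_age(0.02, rate = 0.013)$T_myr)
  expect_error(estimate_age(0.1, rate = 0), "positive")
  expect_error(estimate_age(-0.1), "non-negative")
})

test_that("LTR pairs extract 1-based inclusive, reverse-complemented on minus strand", {
  genome <- Biostrings::DNAStringSet(c(chrA = "AAAACGTACGTTTT"))
  coords <- data.frame(te_id = "te1", chrom = "chrA",
                       left_start = 5, left_end = 8,
                       right_start = 9, right_end = 12,
                       stringsAsFactors = FALSE)
  pairs <- extract_ltr_pairs(genome, coords)
  expect_equal(pairs[[1]]$left, "CGTA")
  expect_equal(pairs[[1]]$right, "CGTT")

  coords$strand <- "-"
  rc <- extract_ltr_pairs(genome, coords)
  expect_equal(rc[[1]]$left, "TACG")   # revcomp of CGTA
  expect_equal(rc[[1]]$right, "AACG")  # revcomp of CGTT

  coords$right_end <- 99
  expect_error(extract_ltr_pairs(genome, coords), "te1")
})

test_that("paired FASTA round-trips LTR pairs", {
  sim <- simulate_ltr_pairs(n = 3, true_t_myr = 0.5, length = 80, seed = 71)
  path <- tempfile(fileext = ".fa")
  write_ltr_fasta(sim$pairs, path)
  back <- read_ltr_fasta(path)
  expect_equal(vapply(back, `[[`, "", "te_id"),
               vapply(sim$pairs, `[[`, "", "te_id"))
  expect_equal(vapply(back, `[[`, "", "left"),
               vapply(sim$pairs, `[[`, "", "left"))
})

test_that("the age table flags saturated pairs instead of dropping them", {
  sat <- ltr_pair("sat", strrep("A", 60), strrep("C", 60))
  ok <- ltr_pair("ok", strrep("ACGT", 30), strrep("ACGT", 30))
  tab <- ltr_age_table(list(ok, sat))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$saturated, c(FALSE, TRUE))
  expect_true(is.na(tab$T_myr[2]))
  expect_equal(attr(tab, "n_saturated"), 1L)
  expect_equal(tab$T_myr[1], 0)
})
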