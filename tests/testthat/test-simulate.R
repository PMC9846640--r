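test_that("generators are pure functions of parameters and seed", {
  f1 <- simulate_syri_vcf(n_variants = 100, seed = 3,
                          path = tempfile(fileext = ".vcf"))
  f2 <- simulate_syri_vcf(n_variants = 100, seed = 3,
                          path = tempfile(fileext = ".vcf"))
  expect_identical(readLines(f1$path), readLines(f2$path))
  expect_identical(f1$truth, f2$truth)

  o1 <- simulate_occupancy(5, 3, 4, 5, seed = 7)
  o2 <- simulate_occupancy(5, 3, 4, 5, seed = 7)
  expect_identical(unclass(o1$table), unclass(o2$table))

  p1 <- simulate_pav_on_tree(balanced10_newick(), 50, 0.2, seed = 29)
  p2 <- simulate_pav_on_tree(balanced10_newick(), 50, 0.2, seed = 29)
  expect_identical(p1$pav, p2$pav)

  l1 <- simulate_ltr_pairs(n = 2, length = 100, seed = 37)
  l2 <- simulate_ltr_pairs(n = 2, length = 100, seed = 37)
  expect_identical(l1$pairs[[1]]$left, l2$pairs[[1]]$left)

  e1 <- simulate_enrichment(n_pop = 100, n_terms = 5, n_study = 10,
                            term_size = 10, seed = 43)
  e2 <- simulate_enrichment(n_pop = 100, n_terms = 5, n_study = 10,
                            term_size = 10, seed = 43)
  expect_identical(e1$study, e2$study)
  expect_identical(e1$annotation, e2$annotation)
  # the global RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_ltr_pairs(n = 1, length = 50, seed = 5))
  expect_identical(runif(1), before)
})

test_that("a clean caller file makes normalization a no-op", {
  sim <- simulate_syri_vcf(n_variants = 120, dup_rate = 0, frag_rate = 0,
                           seed = 2)
  vs <- read_syri_vcf(sim$path, "g")
  expect_equal(sim$truth$duplicates, 0L)
  expect_equal(sim$truth$fragment_clusters, 0L)
  norm <- normalize_variants(vs)
  expect_equal(nrow(norm), nrow(vs))
  expect_equal(variant_key(norm), variant_key(vs))
})

test_that("planned occupancy scenarios classify exactly as requested", {
  sim <- simulate_occupancy(n_genotypes = 10, n_core = 62, n_shell = 8556,
                            n_cloud = 16087, seed = 7)
  s <- class_summary(sim$table)
  expect_equal(setNames(s$count, s$class),
               c(CORE = 62, SHELL = 8556, CLOUD = 16087))

  no_shell <- simulate_occupancy(4, 5, 0, 5, seed = 9)
  s2 <- class_summary(no_shell$table)
  expect_equal(s2$count[s2$class == "SHELL"], 0)

  expect_error(simulate_occupancy(4, 0, 0, 0, seed = 1), "not all zero")
})

test_that("shell occupancy levels follow the supplied spectrum shape", {
  sim <- simulate_occupancy(n_genotypes = 10, n_core = 50, n_shell = 3000,
                            n_cloud = 100, seed = 17)
  spec <- occupancy_spectrum(sim$table)
  shell_levels <- spec[as.character(2:9)]
  # default shape: mode at 9 of 10, secondary at 2 of 10
  expect_equal(names(which.max(shell_levels)), "9")
  expect_equal(names(which.max(shell_levels[-8])), "2")
})

test_that("PAV simulation respects its limits and rejects bad trees", {
  low <- simulate_pav_on_tree(balanced10_newick(), 300, loss_rate = 0.001,
                              seed = 5)
  expect_gte(mean(low$pav), 0.99)
  expect_true(all(rowSums(low$pav) >= 1))
  expect_error(simulate_pav_on_tree("((A:1,B:1", 10, 0.2, seed = 1),
               "malformed")
  expect_error(simulate_pav_on_tree(balanced10_newick(), 10, 1.5, seed = 1),
               "loss_rate")
})

test_that("LTR pairs at age zero are identical and kappa shapes P vs Q", {
  zero <- simulate_ltr_pairs(n = 5, true_t_myr = 0, length = 200, seed = 11)
  for (p in zero$pairs) expect_identical(p$left, p$right)
  tab <- ltr_age_table(zero$pairs)
  expect_equal(tab$T_myr, rep(0, 5))

  tv_rich <- simulate_ltr_pairs(n = 30, true_t_myr = 3, kappa = 0.5,
                                length = 1000, seed = 13)
  tab2 <- ltr_age_table(tv_rich$pairs)
  expect_gt(mean(tab2$Q), mean(tab2$P))

  ts_rich <- simulate_ltr_pairs(n = 30, true_t_myr = 3, kappa = 8,
                                length = 1000, seed = 13)
  tab3 <- ltr_age_table(ts_rich$pairs)
  expect_gt(mean(tab3$P), mean(tab3$Q))
})

test_that("enrichment generator validates sizes and plants its terms", {
  expect_error(simulate_enrichment(n_pop = 50, n_study = 60, seed = 1),
               "n_study")
  expect_error(simulate_enrichment(fold = 0.5, seed = 1), "fold")
  sim <- simulate_enrichment(n_pop = 500, n_terms = 10, planted_terms = 2,
                             fold = 10, n_study = 50, term_size = 25,
                             seed = 43)
  expect_length(sim$truth$planted, 2L)
  expect_true(all(sim$truth$planted %in% sim$annotation$term_id))
  expect_true(all(sim$study %in% sim$population))
  # planted-term genes are over-represented in the study set
  planted_genes <- unique(sim$annotation$gene_id[
    sim$annotation$term_id %in% sim$truth$planted])
  frac_study <- mean(sim$study %in% planted_genes)
  frac_pop <- mean(sim$population %in% planted_genes)
  expect_gt(frac_study, frac_pop)
})
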