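test_that("parsing the caller dialect preserves every record and its type", {
  vs <- toy_variant_set()
  expect_s3_class(vs, "variant_set")
  expect_equal(nrow(vs), 5L)
  expect_equal(as.integer(table(vs$vtype)[c("SNP", "DEL", "INS")]),
               c(2L, 2L, 1L))
  # INFO keys survive
  expect_equal(vs$chrb[vs$id == "v1"], "Chr01")
  expect_equal(vs$duptype[vs$id == "v3"], "copy")
  # sorted by (chrom, pos)
  expect_false(is.unsorted(order(vs$chrom, vs$pos)))
})

test_that("header-only files yield an empty variant set", {
  vs <- read_syri_vcf(write_vcf_fixture(character()), "empty")
  expect_equal(nrow(vs), 0L)
  expect_equal(attr(vs, "genotype"), "empty")
})

test_that("malformed lines fail with the offending line number", {
  path <- write_vcf_fixture(c(toy_vcf_body, "Chr03\t10\tbad\tA"))
  expect_error(suppressWarnings(read_syri_vcf(path, "g")), "line 8")
})

test_that("unknown symbolic ALT codes are flagged OTHER with a warning", {
  path <- write_vcf_fixture("Chr01\t10\tv\tA\t<WEIRD>\t.\tPASS\t.")
  expect_warning(vs <- read_syri_vcf(path, "g"), "OTHER")
  expect_equal(vs$vtype, "OTHER")
  expect_equal(vs$size_class, "OTHER")
})

test_that("parsing a generated file reproduces the generator's type table", {
  sim <- simulate_syri_vcf(n_variants = 200, dup_rate = 0, frag_rate = 0,
                           seed = 7)
  vs <- read_syri_vcf(sim$path, "g")
  expect_equal(nrow(vs), 200L)
  got <- as.list(table(factor(vs$vtype,
                              levels = names(sim$truth$written_type_counts))))
  expect_equal(lapply(got, as.integer),
               lapply(sim$truth$written_type_counts, as.integer))
})

test_that("deduplication keeps one record per identity key", {
  df <- data.frame(chrom = "Chr01", pos = c(100L, 100L),
                   ref = "ATT", alt = "A", vtype = "DEL",
                   stringsAsFactors = FALSE)
  vs <- variant_set(df, "g")
  expect_equal(nrow(deduplicate_variants(vs)), 1L)

  distinct <- variant_set(data.frame(chrom = "Chr01", pos = c(1L, 2L, 3L),
                                     ref = "A", alt = "G", vtype = "SNP"),
                          "g")
  expect_equal(nrow(deduplicate_variants(distinct)), 3L)
})

test_that("deduplication removes exactly the injected duplicates", {
  sim <- simulate_syri_vcf(n_variants = 500, dup_rate = 0.05, frag_rate = 0,
                           seed = 3)
  vs <- read_syri_vcf(sim$path, "g")
  dd <- deduplicate_variants(vs)
  expect_equal(sim$truth$duplicates, 25L)
  # count(out) = count(in) - injected duplicates, exactly
  expect_equal(nrow(vs) - nrow(dd), sim$truth$duplicates)
  expect_equal(nrow(dd), sim$truth$n_variants)
  # idempotent
  expect_equal(nrow(deduplicate_variants(dd)), nrow(dd))
})

test_that("fragmented insertions merge by anchor with concatenated inserts", {
  df <- data.frame(chrom = "Chr02", pos = c(500L, 500L),
                   ref = "A", alt = c("AACG", "ATT"), vtype = "INS",
                   stringsAsFactors = FALSE)
  vs <- variant_set(df, "g")
  merged <- merge_fragmented_insertions(vs, gap_tol = 0)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$alt, "AACGTT")   # inserted parts ACG + TT
  expect_equal(merged$size, 5L)
  expect_equal(merged$fragments, 2L)

  single <- variant_set(df[1, ], "g")
  expect_equal(as.data.frame(merge_fragmented_insertions(single, 0))[, 1:7],
               as.data.frame(single)[, 1:7])
  expect_error(merge_fragmented_insertions(vs, -1), "gap_tol")
})

test_that("fragment merging recovers the generator's clusters and conserves inserted length", {
  sim <- simulate_syri_vcf(n_variants = 400, dup_rate = 0.04,
                           frag_rate = 0.5, seed = 11)
  vs <- read_syri_vcf(sim$path, "g")
  dd <- deduplicate_variants(vs)
  merged <- merge_fragmented_insertions(dd, gap_tol = 0)
  expect_gt(sim$truth$fragment_clusters, 0L)
  expect_equal(sum(merged$fragments > 1L), sim$truth$fragment_clusters)
  expect_equal(nrow(merged), sim$truth$n_variants)
  ins <- merged[merged$vtype == "INS", ]
  expect_equal(sum(nchar(ins$alt) - nchar(ins$ref)),
               sim$truth$total_insert_len)
  # idempotent
  again <- merge_fragmented_insertions(merged, gap_tol = 0)
  expect_equal(as.data.frame(again)[, 1:8], as.data.frame(merged)[, 1:8])
})

test_that("the 50 bp rule separates small indels from SVs", {
  expect_equal(classify_size("DEL", 49), "SMALL_INDEL")
  expect_equal(classify_size("INS", 50), "SV")
  expect_equal(classify_size("SNP", 0), "SNP")
  expect_equal(classify_size(c("INV", "TRANS"), c(500, 1000)),
               c("OTHER", "OTHER"))
  expect_error(classify_size("DEL", -1), "non-negative")
})

test_that("splitting by type partitions the set", {
  df <- data.frame(chrom = "Chr01", pos = 1:5,
                   ref = c("A", "C", "G", "ATT", "GCC"),
                   alt = c("G", "T", "A", "A", "G"),
                   vtype = c("SNP", "SNP", "SNP", "DEL", "DEL"),
                   stringsAsFactors = FALSE)
  parts <- split_by_type(variant_set(df, "g"))
  expect_named(parts, c("SNP", "DEL"))
  expect_equal(vapply(parts, nrow, 0L), c(SNP = 3L, DEL = 2L))

  empty <- variant_set(df[0, ], "g")
  expect_length(split_by_type(empty), 0L)

  sim <- simulate_syri_vcf(n_variants = 300, dup_rate = 0, frag_rate = 0,
                           seed = 5)
  parts <- split_by_type(read_syri_vcf(sim$path, "g"))
  counts <- sim$truth$normalized_type_counts
  for (tp in names(parts))
    expect_equal(nrow(parts[[tp]]), as.integer(counts[[tp]]))
  expect_equal(sum(vapply(parts, nrow, 0L)), 300L)
})

test_that("normalized sets round-trip through standards-conformant VCF", {
  sim <- simulate_syri_vcf(n_variants = 150, dup_rate = 0.1, frag_rate = 0.3,
                           seed = 19)
  norm <- normalize_variants(read_syri_vcf(sim$path, "g"))
  out <- tempfile(fileext = ".vcf")
  write_variant_vcf(norm, out)
  back <- read_syri_vcf(out, "g")
  expect_equal(variant_key(back), variant_key(norm))
  expect_equal(back$size, norm$size)
})
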