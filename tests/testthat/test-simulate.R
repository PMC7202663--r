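test_that("make_reference hits the requested composition deterministically", {
  r1 <- make_reference(1e6, 0.5, seed = 5)
  r2 <- make_reference(1e6, 0.5, seed = 5)
  expect_identical(r1, r2)
  gc <- function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% c("G", "C"))
  }
  expect_lt(abs(gc(r1[[1]]) - 0.5), 3 * sqrt(0.25 / 1e6))
  r3 <- make_reference(1e6, 0.36, seed = 6)
  expect_lt(abs(gc(r3[[1]]) - 0.36), 3 * sqrt(0.36 * 0.64 / 1e6))
})

test_that("implant_deletion constructs exactly the requested micro-homology", {
  ref <- make_reference(5000, seed = 10)
  for (m in c(0L, 1L, 3L, 5L)) {
    res <- implant_deletion(ref, "chrS", start = 1000L + 300L * m, size = 80L,
                            mh_len = m, minus1_base = "C", seed = 20 + m)
    ref <- res$ref
    # the emitted record is already normalised
    norm <- normalize_deletions(res$record, ref)
    expect_equal(norm$start, res$record$start)
    ctx <- build_junction_context(ref, "chrS", res$record$start,
                                  res$record$end, w = 10)
    expect_equal(mh_length(ctx), m)
    expect_equal(substr(res$record$ref_allele, 1, 1), "C")
  }
  expect_error(implant_deletion(ref, "chrS", 3000L, size = 4L, mh_len = 5L),
               "infeasible")
})

test_that("templated implants close the loop with insertion classification", {
  ref <- make_reference(4000, seed = 30)
  res <- implant_deletion(ref, "chrS", start = 2000L, size = 100L,
                          mh_len = 2L, insert = "templated", insert_len = 6L,
                          seed = 31)
  expect_equal(classify_insertions(res$record, res$ref)[1], "templated")
  origin <- substr(res$ref[["chrS"]], res$truth$origin_start,
                   res$truth$origin_end)
  probe <- if (res$truth$origin_strand == "+") origin else revcomp(origin)
  expect_equal(probe, res$record$alt_allele)
})

test_that("zero rates produce an empty table and same seeds identical output", {
  cfg0 <- sim_config(genome_length = 5e4, n_lines = 3,
                     class_rates = c(SNV = 0, microsatellite_indel = 0,
                                     deletion_50_500 = 0), seed = 40)
  sim0 <- simulate_ma_lines(cfg0)
  expect_equal(nrow(sim0$variants), 0L)
  cfg <- sim_config(genome_length = 2e5, n_lines = 4, seed = 41)
  a <- simulate_ma_lines(cfg)
  b <- simulate_ma_lines(cfg)
  expect_identical(a$ref, b$ref)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth, b$truth)
})

test_that("per-line event counts follow the configured Poisson rates", {
  cfg <- sim_config(genome_length = 3e6, n_lines = 120,
                    generations_per_line = 40, seed = 42)
  sim <- simulate_ma_lines(cfg)
  T_total <- sum(sim$lines$generations)
  cls <- classify_variants(normalize_deletions(sim$variants, sim$ref), sim$ref)
  for (cl in c("SNV", "microsatellite_indel", "deletion_50_500")) {
    lambda <- cfg$class_rates[[cl]]
    se <- sqrt(lambda / T_total)
    expect_lt(abs(sum(cls == cl) / T_total - lambda), 3 * se)
  }
})

test_that("emitted deletions survive a file round trip unchanged", {
  cfg <- sim_config(genome_length = 3e5, n_lines = 6, seed = 43)
  dir <- withr::local_tempdir()
  sim <- simulate_ma_lines(cfg, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("reference.fa", "variants.tsv",
                                               "truth.tsv", "lines.tsv")))))
  ref <- read_genome(file.path(dir, "reference.fa"))
  expect_identical(ref, sim$ref)
  back <- read_variant_table(file.path(dir, "variants.tsv"), ref = ref)
  expect_equal(back$start, sim$variants$start)
  # every emitted deletion is already in maximal-5'-conservation form
  norm <- normalize_deletions(back, ref)
  expect_true(all(norm$shifted_by[nchar(norm$ref_allele) >= 50] == 0L))
})

test_that("generation counts respect the configured law", {
  cfg <- sim_config(genome_length = 2e5, n_lines = 40,
                    class_rates = c(SNV = 0.01, microsatellite_indel = 0,
                                    deletion_50_500 = 0), seed = 44)
  sim <- simulate_ma_lines(cfg)
  expect_true(all(sim$lines$generations >= 40 & sim$lines$generations <= 60))
  cfg_fix <- sim_config(genome_length = 2e5, n_lines = 5,
                        generations_per_line = 45, seed = 45)
  expect_true(all(simulate_ma_lines(cfg_fix)$lines$generations == 45L))
})

test_that("contaminated events are shared across lines and filtered out", {
  cfg <- sim_config(genome_length = 1e6, n_lines = 10,
                    shared_fraction = 0.3, seed = 46)
  sim <- simulate_ma_lines(cfg)
  res <- filter_de_novo(sim$variants)
  expect_gt(nrow(res$rejected), 0L)
  expect_true(all(grepl("not de novo", res$rejected$reason)))
  # every kept record is private to one line
  key <- with(res$kept, paste(chrom, start, end, ref_allele, alt_allele))
  expect_false(any(duplicated(key)))
})

test_that("truth labels agree with the analysis modules (closed loop)", {
  cfg <- sim_config(genome_length = 2e6, n_lines = 60,
                    generations_per_line = 40, seed = 47)
  sim <- simulate_ma_lines(cfg)
  tab <- normalize_deletions(sim$variants, sim$ref)
  del <- tab[nchar(tab$ref_allele) >= 50, , drop = FALSE]
  key <- paste(del$start, del$end)
  tr <- sim$truth[match(key, paste(sim$truth$start, sim$truth$end)), ]
  expect_false(any(is.na(tr$deletion_size)))
  ctxs <- contexts_from_table(del, sim$ref, w = 10)
  mh <- vapply(ctxs, mh_length, integer(1))
  expect_equal(mh, pmin(tr$true_mh_length, 10L))
  cats <- classify_insertions(del, sim$ref)
  expect_equal(unname(cats[tr$insert_type == "templated"]),
               rep("templated", sum(tr$insert_type == "templated")))
  expect_equal(unname(cats[tr$insert_type == "none"]),
               rep("simple", sum(tr$insert_type == "none")))
})
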