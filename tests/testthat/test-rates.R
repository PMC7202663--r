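test_that("the de novo filter applies all three acceptance rules", {
  shared <- rbind(toy_row(start = 10L, end = 10L, ref_allele = "A",
                          alt_allele = "G", subpop = "L1"),
                  toy_row(start = 10L, end = 10L, ref_allele = "A",
                          alt_allele = "G", subpop = "L2"))
  shallow <- toy_row(start = 20L, end = 20L, ref_allele = "C",
                     alt_allele = "T", depth = 4L)
  oneside <- toy_row(start = 30L, end = 30L, ref_allele = "G",
                     alt_allele = "A", rev = FALSE)
  good <- toy_row(start = 40L, end = 40L, ref_allele = "T",
                  alt_allele = "C", depth = 12L)
  res <- filter_de_novo(rbind(shared, shallow, oneside, good))
  expect_equal(nrow(res$kept), 1L)
  expect_equal(res$kept$start, 40L)
  expect_equal(nrow(res$rejected), 4L)
  expect_match(res$rejected$reason[1], "not de novo")
  expect_match(res$rejected$reason[res$rejected$start == 20], "depth below 5")
  expect_match(res$rejected$reason[res$rejected$start == 30], "both strands")
  # kept + rejected partition the input, and the filter is a fixed point
  expect_equal(nrow(res$kept) + nrow(res$rejected), 5L)
  again <- filter_de_novo(res$kept)
  expect_equal(again$kept, res$kept)
  expect_equal(nrow(again$rejected), 0L)
})

test_that("absent read flags pass or fail according to configuration", {
  rec <- toy_row(start = 5L, end = 5L, ref_allele = "A", alt_allele = "G",
                 fwd = NA, rev = NA, depth = NA_integer_)
  expect_equal(nrow(filter_de_novo(rec)$kept), 1L)
  expect_equal(nrow(filter_de_novo(rec, missing_flags = "fail")$kept), 0L)
})

test_that("rates are counts over generations with exact Poisson intervals", {
  lines <- data.frame(subpop = "L1", genotype = "wt", generations = 45L)
  muts <- do.call(rbind, lapply(1:9, function(i) {
    toy_row(start = i * 10L, end = i * 10L, ref_allele = "A",
            alt_allele = "T", class = "SNV", subpop = "L1",
            generations = 45L)
  }))
  fit <- estimate_rates(muts, lines)
  expect_equal(unname(coef(fit)[["wt:SNV"]]), 0.2)
  ci <- confint(fit)["wt:SNV", ]
  expect_true(ci[["lower"]] <= 0.2 && 0.2 <= ci[["upper"]])
  expect_equal(ci, stats::poisson.test(9, 45)$conf.int[1:2],
               ignore_attr = TRUE)
  # zero-count strata carry a one-sided interval
  zero <- confint(fit)["wt:deletion_50_500", ]
  expect_equal(unname(zero[["lower"]]), 0)
  expect_gt(zero[["upper"]], 0)
  expect_error(estimate_rates(muts, data.frame(subpop = "L1", genotype = "wt",
                                               generations = NA)),
               "positive generation")
})

test_that("pooling lines equals the ratio of summed counts and generations", {
  lines <- data.frame(subpop = c("L1", "L2"), genotype = "wt",
                      generations = c(40L, 60L))
  muts <- rbind(toy_row(start = 10L, end = 10L, ref_allele = "A",
                        alt_allele = "T", class = "SNV", subpop = "L1",
                        generations = 40L),
                toy_row(start = 20L, end = 20L, ref_allele = "A",
                        alt_allele = "T", class = "SNV", subpop = "L2",
                        generations = 60L),
                toy_row(start = 30L, end = 30L, ref_allele = "A",
                        alt_allele = "T", class = "SNV", subpop = "L2",
                        generations = 60L))
  fit <- estimate_rates(muts, lines)
  expect_equal(unname(coef(fit)[["wt:SNV"]]), 3 / 100)
  # line order is irrelevant
  fit2 <- estimate_rates(muts[c(3, 1, 2), ], lines[c(2, 1), ])
  expect_equal(coef(fit2), coef(fit))
})

test_that("rate estimates recover simulated Poisson truth", {
  set.seed(91)
  n_lines <- 200
  lambda <- 0.23
  lines <- data.frame(subpop = sprintf("L%03d", 1:n_lines), genotype = "wt",
                      generations = 40L)
  counts <- rpois(n_lines, lambda * 40)
  total <- sum(counts)
  muts <- data.frame(chrom = "chr1", start = seq_len(total) * 10L,
                     end = seq_len(total) * 10L, ref_allele = "A",
                     alt_allele = "T", class = "SNV", genotype = "wt",
                     subpop = rep(lines$subpop, counts), generations = 40L,
                     fwd = TRUE, rev = TRUE, depth = 30L,
                     stringsAsFactors = FALSE)
  fit <- estimate_rates(muts, lines)
  se <- sqrt(lambda / (n_lines * 40))
  expect_lt(abs(coef(fit)[["wt:SNV"]] - lambda), 3 * se)
  # parametric bootstrap reproduces the counts in expectation
  sims <- simulate(fit, nsim = 200, seed = 1)
  mean_snv <- mean(vapply(sims, function(s) {
    s$n_mutations[s$class == "SNV"]
  }, numeric(1)))
  expect_lt(abs(mean_snv - sum(counts)), 3 * sqrt(sum(counts)))
})

test_that("fold changes follow the conditional binomial construction", {
  fc <- fold_change(300, 100, 10, 100)
  expect_equal(fc$ratio, 30)
  expect_true(fc$conf_int[1] < 30 && 30 < fc$conf_int[2])
  expect_equal(fold_change(7, 50, 7, 50)$ratio, 1)
  inf <- fold_change(5, 100, 0, 100)
  expect_equal(inf$ratio, Inf)
  expect_true(is.finite(inf$conf_int[1]) && inf$conf_int[1] > 0)
})

test_that("fold-change intervals achieve nominal coverage", {
  set.seed(92)
  hits <- 0; n_sim <- 300
  for (i in 1:n_sim) {
    n_a <- rpois(1, 30); n_b <- rpois(1, 10)
    if (n_a + n_b == 0) { hits <- hits + 1; next }
    fc <- fold_change(n_a, 1, n_b, 1)
    if (fc$conf_int[1] <= 3 && 3 <= fc$conf_int[2]) hits <- hits + 1
  }
  # exact intervals are conservative: coverage >= ~95%
  expect_gt(hits / n_sim, 0.93)
})

test_that("mann_whitney_exact reproduces textbook cases", {
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(4, 5, 6), "less")$p, 1 / 20)
  expect_equal(mann_whitney_exact(5, 5)$p, 1)
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(4, 5, 6), "less")$U, 0)
  big <- mann_whitney_exact(rnorm(20), rnorm(20))
  expect_match(big$method, "normal")
})

test_that("exact p-values match the enumeration oracle with and without ties", {
  set.seed(93)
  for (i in 1:40) {
    n_x <- sample(1:5, 1); n_y <- sample(1:5, 1)
    vals <- sample(1:4, n_x + n_y, replace = TRUE)  # heavy ties
    x <- vals[seq_len(n_x)]; y <- vals[-seq_len(n_x)]
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(mann_whitney_exact(x, y, alt)$p, oracle_mw(x, y, alt),
                   info = sprintf("nx=%d ny=%d alt=%s", n_x, n_y, alt))
    }
  }
})

test_that("exact and large-sample p-values agree at moderate n", {
  set.seed(94)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12, 0.3)
    p_exact <- mann_whitney_exact(x, y, exact_max = 24)$p
    p_norm <- mann_whitney_exact(x, y, exact_max = 10)$p
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("size distributions summarise deletions per genotype", {
  tab <- rbind(toy_row(start = 1L, end = 50L, ref_allele = strrep("A", 50)),
               toy_row(start = 100L, end = 199L, ref_allele = strrep("A", 100)),
               toy_row(start = 300L, end = 799L, ref_allele = strrep("A", 500)))
  sd1 <- size_distribution(tab)
  expect_equal(unname(sd1$median[["wt"]]), 100)
  expect_equal(unname(sd1$log10_median[["wt"]]), 2)
  sd2 <- size_distribution(rbind(tab, tab))
  expect_equal(sd2$median, sd1$median)
})

test_that("lesion frequency arithmetic matches its closed form", {
  lf <- lesion_frequency(0.1, 10, 1e8)
  expect_equal(lf$bases_per_event, 1e10)
  lf2 <- lesion_frequency(1, 10, 1e8)
  expect_equal(lf2$bases_per_event, 1e9)
  expect_equal(lf$per_base_rate * lf$bases_per_event, 1)
  # doubling genome size halves the per-base rate
  expect_equal(lesion_frequency(0.1, 10, 2e8)$per_base_rate,
               lf$per_base_rate / 2)
  lf0 <- lesion_frequency(0, 10, 1e8)
  expect_true(is.na(lf0$bases_per_event))
  expect_match(lf0$note, "undefined")
})
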