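test_that("mh_length measures the retained/lost suffix match", {
  # "AATGCTGCAA": deleting 6-8 leaves ...AATGC | TGC... with 3 bp homology
  ref <- c(chr1 = "AATGCTGCAA")
  expect_equal(mh_length(build_junction_context(ref, "chr1", 6, 8, w = 5)), 3L)
  # no match at depth 1
  ref2 <- c(chr1 = "AAAAATGGGGG")
  expect_equal(mh_length(build_junction_context(ref2, "chr1", 6, 6, w = 4)), 0L)
  # through a G run after normalisation
  ref3 <- c(chr1 = "AGGGGT")
  tab <- normalize_deletions(toy_row(start = 2L, end = 3L, ref_allele = "GG"), ref3)
  expect_equal(mh_length(build_junction_context(ref3, "chr1", tab$start,
                                                tab$end, w = 3)), 2L)
})

test_that("mh_length equals the longest-common-suffix oracle on random cases", {
  set.seed(52)
  for (i in 1:400) {
    ref_str <- rand_seq(140)
    w <- sample(3:12, 1)
    s <- sample(20:60, 1)
    e <- s + sample(0:40, 1)
    ctx <- build_junction_context(c(chr1 = ref_str), "chr1", s, e, w = w)
    expect_equal(mh_length(ctx), oracle_mh(ref_str, s, e, w),
                 info = sprintf("s=%d e=%d w=%d", s, e, w))
  }
})

test_that("a single event yields an indicator heatmap with the structural zero", {
  # construct a context with mh exactly 2: retained suffix GC == lost suffix GC
  ref <- c(chr1 = "AAAGCTTTTGCAAAA")   # deletion 6-11: AAAGC | TTTTGC | AAAA
  tab <- normalize_deletions(toy_row(start = 6L, end = 11L,
                                     ref_allele = "TTTTGC"), ref)
  ctx <- build_junction_context(ref, "chr1", tab$start, tab$end, w = 3)
  expect_equal(mh_length(ctx), 2L)
  hm <- mh_heatmap(list(ctx))
  expect_equal(hm$cells["+1", "-1"], 1)
  expect_equal(hm$cells["+2", "-2"], 1)
  expect_equal(hm$cells["-1", "+1"], 0)
  expect_true(all(hm$cells %in% c(0, 1)))
})

test_that("heatmaps are means: duplication and order invariant", {
  set.seed(61)
  ctxs <- replicate(30, rand_ctx(w = 6), simplify = FALSE)
  hm <- mh_heatmap(ctxs)
  hm2 <- mh_heatmap(c(ctxs, ctxs))
  expect_equal(hm$cells, hm2$cells)
  hm3 <- mh_heatmap(ctxs[sample(length(ctxs))])
  expect_equal(hm$cells, hm3$cells)
  expect_error(mh_heatmap(list()), "at least one")
})

test_that("uniform random flanks give 0.25 everywhere except the skew cells", {
  set.seed(62)
  n <- 4000
  ctxs <- replicate(n, rand_ctx(w = 5, normalized = TRUE), simplify = FALSE)
  hm <- mh_heatmap(ctxs)
  expect_equal(hm$cells["-1", "+1"], 0)   # structurally empty under the rule
  others <- hm$cells
  others["-1", "+1"] <- NA
  dev <- abs(others - 0.25)
  bound3 <- 3 * sqrt(0.25 * 0.75 / n)
  bound5 <- 5 * sqrt(0.25 * 0.75 / n)
  # allow the family-wise expected handful of 3-sigma excursions over 100 cells
  expect_lte(sum(dev > bound3, na.rm = TRUE), 4L)
  expect_true(all(dev < bound5, na.rm = TRUE))
})

test_that("the shuffled null is a fixed point on mono-base windows", {
  ctx <- structure(list(w = 4L, chrom = "x", start = 10L, end = 59L,
                        deletion_size = 50L, up_retained = "AAAA",
                        up_lost = "CCCC", down_lost = "GGGG",
                        down_retained = "TTTT"),
                   class = "junction_context")
  obs <- mh_heatmap(list(ctx))
  null <- shuffled_null(list(ctx), n_replicates = 5, seed = 1)
  expect_equal(null$cells, obs$cells)
})

test_that("the shuffled null shows the annotation skew and is reproducible", {
  set.seed(63)
  ctxs <- replicate(800, rand_ctx(w = 5), simplify = FALSE)
  n1 <- shuffled_null(ctxs, n_replicates = 3, seed = 17)
  n2 <- shuffled_null(ctxs, n_replicates = 3, seed = 17)
  expect_equal(n1$cells, n2$cells)
  # re-annotation empties (-1,+1) and elevates (+1,-1) above chance
  expect_equal(n1$cells["-1", "+1"], 0)
  se <- sqrt(0.25 * 0.75 / n1$counts["+1", "-1"])
  expect_gt(n1$cells["+1", "-1"], 0.25 + 3 * se)
})

test_that("compare_cell runs a 2x2 chi-square with the documented behaviour", {
  mk <- function(m, n, w = 2) {
    cells <- matrix(0, 2 * w, 2 * w,
                    dimnames = list(tmejsig:::pos5_labels(w),
                                    tmejsig:::pos3_labels(w)))
    matches <- cells; counts <- cells
    matches["+1", "-1"] <- m; counts["+1", "-1"] <- n
    structure(list(cells = matches / pmax(counts, 1), matches = matches,
                   counts = counts, n_events = n, w = w, source = "t",
                   n_replicates = 1L), class = "mh_heatmap")
  }
  strong <- compare_cell(mk(40, 50), mk(125, 500))
  expect_lt(strong$p, 0.001)
  expect_equal(strong$stars, "***")
  null <- compare_cell(mk(10, 40), mk(10, 40))
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)
  expect_equal(null$stars, "NS")
  # doubling all counts doubles the Pearson statistic
  x1 <- compare_cell(mk(30, 50), mk(100, 400))
  x2 <- compare_cell(mk(60, 100), mk(200, 800))
  expect_equal(x2$statistic, 2 * x1$statistic)
  degenerate <- compare_cell(mk(0, 10), mk(0, 40))
  expect_false(degenerate$applicable)
  expect_equal(degenerate$stars, "inapplicable")
})

test_that("insertions classify by size and mappable origin", {
  set.seed(71)
  ref_str <- rand_seq(400)
  s <- 201L; e <- 280L
  # plant a 5 bp origin 12 bp upstream of the 5' breakpoint
  origin <- substr(ref_str, s - 16, s - 12)
  tab <- toy_row(start = s, end = e, ref_allele = substr(ref_str, s, e),
                 alt_allele = origin)
  expect_equal(classify_insertions(tab, c(chr1 = ref_str))[1], "templated")
  # empty insert
  tab$alt_allele <- ""
  expect_equal(classify_insertions(tab, c(chr1 = ref_str))[1], "simple")
  # a 3 bp insert matching the flank perfectly is still below the size threshold
  tab$alt_allele <- substr(ref_str, s - 3, s - 1)
  expect_equal(classify_insertions(tab, c(chr1 = ref_str))[1], "misc")
  # reverse-complement origins count
  tab$alt_allele <- revcomp(substr(ref_str, e + 5, e + 12))
  expect_equal(classify_insertions(tab, c(chr1 = ref_str))[1], "templated")
})

test_that("insertion classification agrees with the exhaustive search oracle", {
  set.seed(72)
  for (i in 1:200) {
    ref_str <- rand_seq(300)
    s <- sample(100:140, 1); e <- s + sample(10:60, 1)
    insert <- switch(sample(3, 1),
                     "",
                     rand_seq(sample(1:8, 1)),
                     { o <- sample((s - 30):(s + 20), 1)   # sometimes mappable
                       substr(ref_str, o, o + sample(4:7, 1)) })
    tab <- toy_row(start = s, end = e, ref_allele = substr(ref_str, s, e),
                   alt_allele = insert)
    expect_equal(classify_insertions(tab, c(chr1 = ref_str))[1],
                 oracle_insertion(ref_str, s, e, insert),
                 info = sprintf("i=%d insert=%s", i, insert))
  }
})

test_that("junction summaries report fractions that sum to one", {
  set.seed(73)
  ref_str <- rand_seq(2000)
  rows <- lapply(1:12, function(k) {
    s <- 60 + 150 * (k - 1); e <- s + 59
    toy_row(start = s, end = e, ref_allele = substr(ref_str, s, e))
  })
  tab <- do.call(rbind, rows)
  ref <- c(chr1 = ref_str)
  js <- junction_summary(normalize_deletions(tab, ref), ref)
  expect_equal(unname(js$fractions[["simple"]]), 1)
  expect_equal(sum(js$fractions), 1)
  expect_equal(js$n_events, 12L)
  # order permutation leaves the fractions unchanged
  js2 <- junction_summary(normalize_deletions(tab[sample(nrow(tab)), ], ref), ref)
  expect_equal(js$fractions, js2$fractions)
})
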