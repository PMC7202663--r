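# De novo filtering and per-generation mutation-rate estimation for
# mutation-accumulation (MA) lines.

#' Filter candidate variants to de novo calls
#'
#' Applies the acceptance rules for MA-line variants: a record is kept when
#' (i) it is de novo — the identical variant (chrom, start, end, alleles) is
#' supported by exactly one subpopulation; (ii) it is covered by both forward
#' and reverse reads; and (iii) read depth is at least `min_depth`. Every
#' rejected record is annotated with all failed criteria.
#'
#' Read-evidence flags are consumed as given, never recomputed from
#' alignments. When the flags are absent (`NA`, e.g. on synthetic input),
#' `missing_flags` decides whether rules (ii)-(iii) pass vacuously (default)
#' or fail closed.
#'
#' @param tab Variant table with `subpop` labels; `fwd`/`rev`/`depth` optional.
#' @param min_depth Minimum read depth (default 5).
#' @param missing_flags `"pass"` (default) or `"fail"`.
#' @return List with `kept` (a variant table) and `rejected` (the complement,
#'   plus a `reason` column). Together they partition the input, and the
#'   filter is a fixed point on its own `kept` output.
#' @export
filter_de_novo <- function(tab, min_depth = 5L,
                           missing_flags = c("pass", "fail")) {
  missing_flags <- match.arg(missing_flags)
  tab <- coerce_variant_cols(tab)
  key <- paste(tab$chrom, tab$start, tab$end, tab$ref_allele, tab$alt_allele,
               sep = "\r")
  n_subpops <- vapply(split(tab$subpop, key),
                      function(s) length(unique(s)), integer(1))[key]
  vacuous <- missing_flags == "pass"
  ok_denovo <- n_subpops == 1L
  ok_strands <- ifelse(is.na(tab$fwd) | is.na(tab$rev),
                       vacuous, tab$fwd & tab$rev)
  ok_depth <- ifelse(is.na(tab$depth), vacuous, tab$depth >= min_depth)
  reasons <- character(nrow(tab))
  add <- function(reasons, bad, msg) ifelse(bad,
    ifelse(nzchar(reasons), paste(reasons, msg, sep = "; "), msg), reasons)
  reasons <- add(reasons, !ok_denovo, "not de novo (shared across subpopulations)")
  reasons <- add(reasons, !ok_strands, "not covered by both strands")
  reasons <- add(reasons, !ok_depth, sprintf("depth below %d", min_depth))
  keep <- ok_denovo & ok_strands & ok_depth
  rejected <- tab[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[!keep]
  kept <- tab[keep, , drop = FALSE]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

VARIANT_CLASSES <- c("SNV", "microsatellite_indel", "deletion_50_500",
                     "deletion_other", "insertion", "structural")

#' Estimate per-generation mutation rates
#'
#' The MA-line rate estimator: for each genotype and variant class, the
#' mutation count divided by the total number of generations grown across
#' that genotype's lines, with an exact (Garwood) Poisson 95% confidence
#' interval per stratum. Zero-count strata are reported with their one-sided
#' interval.
#'
#' @param tab Variant table of accepted de novo calls; needs a `class` column
#'   (see [classify_variants()]).
#' @param lines Line metadata: data.frame with `subpop`, `genotype`,
#'   `generations` (one row per MA line; every line must have a positive
#'   generation count). Lines without variants still contribute generations.
#' @param classes Class levels to report (default the six standard classes
#'   plus any others present).
#' @param conf_level Confidence level for the Poisson intervals (default 0.95).
#' @return A `rate_table` object; see [coef.rate_table()], [confint.rate_table()],
#'   [predict.rate_table()], [simulate.rate_table()].
#' @examples
#' lines <- data.frame(subpop = "L1", genotype = "wt", generations = 45)
#' muts <- data.frame(chrom = "chr1", start = 1:9, end = 1:9,
#'                    ref_allele = "A", alt_allele = "T", class = "SNV",
#'                    genotype = "wt", subpop = "L1", generations = 45)
#' coef(estimate_rates(muts, lines))  # 9 / 45 = 0.2 per generation
#' @export
estimate_rates <- function(tab, lines, classes = NULL, conf_level = 0.95) {
  tab <- coerce_variant_cols(tab)
  stopifnot(all(c("subpop", "genotype", "generations") %in% names(lines)))
  if (any(is.na(lines$generations)) || any(lines$generations <= 0)) {
    stop("every line needs a positive generation count")
  }
  if (any(is.na(tab$class))) {
    stop("all records need a class; run classify_variants() first")
  }
  orphan <- setdiff(tab$subpop, lines$subpop)
  if (length(orphan)) stop("subpopulation(s) missing from line metadata: ",
                           paste(sQuote(orphan), collapse = ", "))
  if (is.null(classes)) {
    classes <- union(VARIANT_CLASSES, unique(tab$class))
  }
  genotypes <- sort(unique(lines$genotype))
  gen_by_geno <- tapply(lines$generations, lines$genotype, sum)
  nlines_by_geno <- tapply(lines$subpop, lines$genotype,
                           function(s) length(unique(s)))
  grid <- expand.grid(genotype = genotypes, class = classes,
                      stringsAsFactors = FALSE)
  grid$n_mutations <- mapply(function(g, cl) {
    sum(tab$genotype == g & tab$class == cl)
  }, grid$genotype, grid$class)
  grid$total_generations <- as.numeric(gen_by_geno[grid$genotype])
  grid$n_lines <- as.integer(nlines_by_geno[grid$genotype])
  grid$rate <- grid$n_mutations / grid$total_generations
  ci <- t(mapply(function(n, T) {
    stats::poisson.test(n, T, conf.level = conf_level)$conf.int / 1
  }, grid$n_mutations, grid$total_generations))
  grid$ci_lo <- ci[, 1]
  grid$ci_hi <- ci[, 2]
  structure(list(table = grid, conf_level = conf_level,
                 ci_method = "exact Poisson (Garwood)",
                 lines = lines),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat("per-generation mutation rates (", x$ci_method, ", ",
      format(100 * x$conf_level), "% CI)\n", sep = "")
  shown <- x$table[x$table$n_mutations > 0 | x$table$class %in%
                     c("SNV", "microsatellite_indel", "deletion_50_500"), ]
  out <- data.frame(genotype = shown$genotype, class = shown$class,
                    n = shown$n_mutations, generations = shown$total_generations,
                    rate = signif(shown$rate, 3),
                    CI = sprintf("[%.3g, %.3g]", shown$ci_lo, shown$ci_hi))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rate_table <- function(object, ...) {
  tab <- object$table
  cat("rate table:", length(unique(tab$genotype)), "genotype(s),",
      length(unique(tab$class)), "classes,",
      sum(tab$n_mutations), "mutations total\n")
  per_geno <- aggregate(cbind(n_mutations = tab$n_mutations),
                        by = list(genotype = tab$genotype), FUN = sum)
  per_geno$total_generations <- as.numeric(
    tapply(tab$total_generations, tab$genotype, max)[per_geno$genotype])
  per_geno$overall_rate <- per_geno$n_mutations / per_geno$total_generations
  print(per_geno, row.names = FALSE)
  invisible(object)
}

#' Extract stratum rates
#'
#' @param object A `rate_table`.
#' @param ... Unused.
#' @return Named numeric vector of rates (`genotype:class`).
#' @export
coef.rate_table <- function(object, ...) {
  stats::setNames(object$table$rate,
                  paste(object$table$genotype, object$table$class, sep = ":"))
}

#' Confidence intervals for stratum rates
#'
#' @param object A `rate_table`.
#' @param parm Optional subset of `genotype:class` names.
#' @param level Ignored; the level is fixed at fit time.
#' @param ... Unused.
#' @return Two-column matrix of interval bounds.
#' @export
confint.rate_table <- function(object, parm = NULL, level = NULL, ...) {
  nm <- paste(object$table$genotype, object$table$class, sep = ":")
  ci <- cbind(lower = object$table$ci_lo, upper = object$table$ci_hi)
  rownames(ci) <- nm
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Expected mutation counts for new lines
#'
#' @param object A `rate_table`.
#' @param newdata Data.frame with `genotype` and `generations`.
#' @param ... Unused.
#' @return Matrix of expected counts (rows = newdata rows, cols = classes).
#' @export
predict.rate_table <- function(object, newdata, ...) {
  tab <- object$table
  classes <- unique(tab$class)
  out <- sapply(classes, function(cl) {
    r <- stats::setNames(tab$rate[tab$class == cl], tab$genotype[tab$class == cl])
    unname(r[newdata$genotype] * newdata$generations)
  })
  out <- matrix(out, nrow = nrow(newdata), dimnames = list(NULL, classes))
  out
}

#' Simulate mutation counts from fitted rates
#'
#' Draws Poisson counts per stratum at the fitted rates and the observed
#' total generations — a parametric bootstrap of the count table.
#'
#' @param object A `rate_table`.
#' @param nsim Number of simulated count tables.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of data.frames shaped like `object$table[, c("genotype",
#'   "class", "n_mutations")]`.
#' @export
simulate.rate_table <- function(object, nsim = 1, seed = NULL, ...) {
  tab <- object$table
  with_seed(seed, lapply(seq_len(nsim), function(s) {
    data.frame(genotype = tab$genotype, class = tab$class,
               n_mutations = stats::rpois(nrow(tab),
                                          tab$rate * tab$total_generations))
  }))
}

#' Rate ratio between two Poisson strata
#'
#' Fold change between two rates, with a confidence interval from the
#' conditional binomial method: given the two counts' total, the first count
#' is binomial with success probability determined by the rate ratio and the
#' exposure split, so an exact binomial interval for that probability maps to
#' an exact interval for the ratio.
#'
#' @param n_a,t_a Count and total generations for the numerator stratum.
#' @param n_b,t_b Count and total generations for the denominator stratum.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `ratio`, `conf_int`, the two rates, and `method`. A zero
#'   denominator count yields an infinite ratio with a finite one-sided lower
#'   bound.
#' @export
fold_change <- function(n_a, t_a, n_b, t_b, conf_level = 0.95) {
  stopifnot(t_a > 0, t_b > 0, n_a >= 0, n_b >= 0)
  if (n_a + n_b == 0) stop("both counts are zero; the ratio is undefined")
  bt <- stats::binom.test(n_a, n_a + n_b, p = t_a / (t_a + t_b),
                          conf.level = conf_level)
  p_ci <- bt$conf.int
  to_ratio <- function(p) (p / (1 - p)) * (t_b / t_a)
  list(ratio = if (n_b > 0) (n_a / t_a) / (n_b / t_b) else Inf,
       conf_int = c(to_ratio(p_ci[1]), to_ratio(p_ci[2])),
       rate_a = n_a / t_a, rate_b = n_b / t_b,
       method = "conditional binomial (exact)")
}

#' Deletion size distribution
#'
#' @param tab Variant table; only deletion rows are used.
#' @param by Grouping column (default `"genotype"`).
#' @return List with `sizes` (data.frame of group, size, log10_size),
#'   `median` and `log10_median` per group, and `n` per group.
#' @export
size_distribution <- function(tab, by = "genotype") {
  tab <- coerce_variant_cols(tab)
  del <- tab[is_deletion_row(tab), , drop = FALSE]
  if (!nrow(del)) stop("no deletions in the table")
  sizes <- data.frame(group = del[[by]], size = nchar(del$ref_allele))
  sizes$log10_size <- log10(sizes$size)
  med <- tapply(sizes$size, sizes$group, stats::median)
  list(sizes = sizes,
       median = med,
       log10_median = log10(med),
       n = as.integer(table(sizes$group)[names(med)]))
}

#' Lesion frequency implied by a deletion rate
#'
#' The arithmetic connecting a per-generation deletion rate to a per-base,
#' per-replication lesion frequency: with `d` deletions per generation, `m`
#' cell divisions per generation and a genome of `g` bases, the per-base rate
#' is `d / (m * g)` and one event occurs per `m * g / d` bases replicated.
#' Under the reading that every unbypassable replication block in a
#' TLS-deficient animal becomes a deletion, this measures how rare such
#' blocks are.
#'
#' @param deletions_per_generation Deletion rate per animal generation.
#' @param divisions_per_generation Germline cell divisions per generation.
#' @param genome_size Genome size in bases.
#' @return A `lesion_frequency` list: the inputs plus `per_base_rate` and
#'   `bases_per_event` (satisfying `per_base_rate * bases_per_event == 1`
#'   exactly). A zero deletion rate is reported explicitly
#'   (`bases_per_event = NA` with a note), not as a division error.
#' @examples
#' lesion_frequency(0.1, 10, 1e8)$bases_per_event  # 1e10
#' @export
lesion_frequency <- function(deletions_per_generation,
                             divisions_per_generation, genome_size) {
  stopifnot(deletions_per_generation >= 0, divisions_per_generation > 0,
            genome_size > 0)
  pbr <- deletions_per_generation / (divisions_per_generation * genome_size)
  out <- list(deletions_per_generation = deletions_per_generation,
              divisions_per_generation = divisions_per_generation,
              genome_size = genome_size,
              per_base_rate = pbr,
              bases_per_event = if (pbr > 0) 1 / pbr else NA_real_,
              note = if (pbr > 0) NULL else
                "zero deletion rate: bases_per_event undefined")
  class(out) <- "lesion_frequency"
  out
}

#' @export
print.lesion_frequency <- function(x, ...) {
  cat(sprintf("%.3g deletions/generation over %g divisions x %.3g bases\n",
              x$deletions_per_generation, x$divisions_per_generation,
              x$genome_size))
  if (is.na(x$bases_per_event)) {
    cat(" ", x$note, "\n")
  } else {
    cat(sprintf("  per-base rate %.3g  (1 event per %.3g bases replicated)\n",
                x$per_base_rate, x$bases_per_event))
  }
  invisible(x)
}
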