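# Synthetic MA-line generator: emits a reference genome and per-line variant
# tables with the statistical structure the analysis assumes (Poisson class
# rates per generation, 50-500 bp deletions with configurable micro-homology,
# templated inserts copied from the breakpoint vicinity, and an optional
# cytosine bias at the first deleted base emulating guanine-lesion anchoring
# on the template strand), together with ground-truth labels.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Assembles and validates the parameters of [simulate_ma_lines()]. Defaults
#' describe a wild-type-like MA experiment: class rates of 0.23 SNVs, 0.04
#' microsatellite indels and 0.04 deletions (50-500 bp) per animal
#' generation; lines grown for a number of generations drawn uniformly from
#' 40-60; deletion sizes log-uniform on [50, 500]; micro-homology lengths
#' geometric; and a neutral cytosine probability at the first deleted base
#' (0.25, matching the default uniform-composition reference).
#'
#' @param genome_length Reference length in bp.
#' @param gc_content GC fraction of the reference (0.36 mimics the
#'   C. elegans genome).
#' @param n_lines Number of independent MA lines.
#' @param generations_per_line `NULL` (draw uniformly from
#'   `generations_range`) or a fixed positive integer.
#' @param generations_range Two integers, inclusive bounds of the uniform
#'   generation draw (default 40-60).
#' @param class_rates Named per-generation rates for `SNV`,
#'   `microsatellite_indel` and `deletion_50_500`.
#' @param deletion_size_law List with `min`, `max` (bp) and `shape`
#'   (`"log_uniform"` or `"uniform"`).
#' @param mh_length_law List with geometric parameter `p` and `cap`.
#' @param insert_prob Probability a deletion carries an insert.
#' @param insert_templated_prob Probability an insert is templated (copied
#'   from within 40 bp of a breakpoint, either strand) rather than random.
#' @param insert_len_law Integer range `c(min, max)` for insert lengths;
#'   templated inserts are drawn from `max(5, min)..max` so they are large
#'   enough to be mapped to their origin.
#' @param minus1_c_bias Probability that the first deleted base is forced to
#'   be C at the lesion-anchored junction.
#' @param anchor_randomize If `TRUE`, the anchored junction is chosen at
#'   random per event instead of always being the 5' junction of the top
#'   strand.
#' @param shared_fraction Fraction of events duplicated into a second line
#'   (contamination; they then fail the de novo filter). Default 0.
#' @param genotype Genotype label attached to all lines.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6, gc_content = 0.5,
                       n_lines = 10L, generations_per_line = NULL,
                       generations_range = c(40L, 60L),
                       class_rates = c(SNV = 0.23,
                                       microsatellite_indel = 0.04,
                                       deletion_50_500 = 0.04),
                       deletion_size_law = list(min = 50L, max = 500L,
                                                shape = "log_uniform"),
                       mh_length_law = list(p = 0.5, cap = 8L),
                       insert_prob = 0.3, insert_templated_prob = 0.5,
                       insert_len_law = c(min = 1L, max = 12L),
                       minus1_c_bias = 0.25, anchor_randomize = FALSE,
                       shared_fraction = 0, genotype = "sim", seed = 1L) {
  stopifnot(genome_length >= 1000, gc_content > 0, gc_content < 1,
            n_lines >= 1, all(class_rates >= 0),
            deletion_size_law$min >= 1,
            deletion_size_law$max >= deletion_size_law$min,
            mh_length_law$p > 0, mh_length_law$p <= 1, mh_length_law$cap >= 0,
            insert_prob >= 0, insert_prob <= 1,
            insert_templated_prob >= 0, insert_templated_prob <= 1,
            minus1_c_bias >= 0, minus1_c_bias <= 1,
            shared_fraction >= 0, shared_fraction < 1)
  if (!all(c("SNV", "microsatellite_indel", "deletion_50_500") %in%
             names(class_rates))) {
    stop("class_rates needs SNV, microsatellite_indel and deletion_50_500")
  }
  if (!is.null(generations_per_line) && generations_per_line <= 0) {
    stop("generations_per_line must be positive")
  }
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content, n_lines = as.integer(n_lines),
                 generations_per_line = generations_per_line,
                 generations_range = as.integer(generations_range),
                 class_rates = class_rates,
                 deletion_size_law = deletion_size_law,
                 mh_length_law = mh_length_law,
                 insert_prob = insert_prob,
                 insert_templated_prob = insert_templated_prob,
                 insert_len_law = c(min = as.integer(min(insert_len_law)),
                                    max = as.integer(max(insert_len_law))),
                 minus1_c_bias = minus1_c_bias,
                 anchor_randomize = anchor_randomize,
                 shared_fraction = shared_fraction,
                 genotype = genotype, seed = as.integer(seed)),
            class = "sim_config")
}

base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

#' Generate a random reference sequence
#'
#' I.i.d. bases at the requested GC content; deterministic given the seed.
#'
#' @param length Sequence length in bp.
#' @param gc_content GC fraction.
#' @param seed Optional integer seed.
#' @param chrom Name of the emitted sequence (default `"chrS"`).
#' @return Named character vector of length one (a genome usable with
#'   [extract_window()] etc.).
#' @export
make_reference <- function(length, gc_content = 0.5, seed = NULL,
                           chrom = "chrS") {
  stopifnot(length >= 1, gc_content > 0, gc_content < 1)
  ch <- with_seed(seed,
                  sample(BASES, length, replace = TRUE,
                         prob = base_probs(gc_content)))
  stats::setNames(c2s(ch), chrom)
}

rnd_bases <- function(n, gc) sample(BASES, n, replace = TRUE, prob = base_probs(gc))

pick_other <- function(base) sample(setdiff(BASES, base), 1L)

# --- core junction constructor ------------------------------------------
# Rewrites reference content (held as a character vector inside `env$ch`)
# around a deletion of positions s..e so that, under maximal 5' conservation,
# the event is already normalised, has micro-homology exactly `mh_len`, and
# carries `minus1_base` as the first deleted base of the anchored junction.
implant_into <- function(env, s, size, mh_len, insert_type, insert_len,
                         minus1_base, anchor_side, gc, search_window = 40L) {
  e <- s + size - 1L
  if (mh_len > size) stop("infeasible: micro-homology cannot exceed the deletion size")
  if (mh_len < 0L) stop("mh_len must be >= 0")
  if (s - mh_len - 1L < 1L || e + 1L > length(env$ch)) {
    stop("locus window too small for the requested construction")
  }
  # lesion-anchored base at position -1 of the anchored junction
  if (anchor_side == "five") {
    env$ch[s] <- minus1_base
  } else {
    env$ch[e] <- comp_chars(minus1_base)  # mirrored reading of the 3' junction
  }
  # micro-homology: retained 5' suffix == deleted 3' suffix
  if (mh_len > 0L) {
    if (mh_len == size && anchor_side == "five") {
      # the suffix includes position s, already pinned to minus1_base
    }
    env$ch[(s - mh_len):(s - 1L)] <- env$ch[(e - mh_len + 1L):e]
  }
  # break the homology at depth mh_len + 1
  pos5 <- s - mh_len - 1L
  pos3 <- e - mh_len
  if (env$ch[pos5] == env$ch[pos3]) env$ch[pos5] <- pick_other(env$ch[pos3])
  # maximal 5' conservation: the emitted annotation must be stable
  if (env$ch[e + 1L] == env$ch[s]) env$ch[e + 1L] <- pick_other(env$ch[s])

  origin <- list(start = NA_integer_, end = NA_integer_, strand = NA_character_)
  insert <- ""
  if (insert_type == "templated") {
    stopifnot(insert_len >= 1L)
    region <- if (sample(c(TRUE, FALSE), 1L)) {
      c(s - search_window, s + search_window - 1L)
    } else {
      c(e - search_window + 1L, e + search_window)
    }
    ostart <- sample(seq(region[1], region[2] - insert_len + 1L), 1L)
    oend <- ostart + insert_len - 1L
    strand <- sample(c("+", "-"), 1L)
    top <- c2s(env$ch[ostart:oend])
    insert <- if (strand == "+") top else revcomp(top)
    origin <- list(start = ostart, end = oend, strand = strand)
  } else if (insert_type == "random") {
    for (try in 1:50) {
      insert <- c2s(rnd_bases(insert_len, gc))
      if (insert_len < 5L) break
      regions <- c(c2s(env$ch[max(1L, s - search_window):(s + search_window - 1L)]),
                   c2s(env$ch[(e - search_window + 1L):min(length(env$ch), e + search_window)]))
      if (!any(grepl(insert, regions, fixed = TRUE)) &&
          !any(grepl(revcomp(insert), regions, fixed = TRUE))) break
      if (try == 50) stop("could not place a vicinity-free random insert")
    }
  }
  list(start = s, end = e, insert = insert, origin = origin)
}

#' Implant a deletion with prescribed junction features
#'
#' Rewrites the local reference so that the deletion starting at `start`,
#' once annotated under maximal 5' conservation, has exactly the requested
#' micro-homology length and first deleted base, and (optionally) carries an
#' insert copied from a recorded origin within 40 bp of a breakpoint. The
#' emitted record is already in normalised form. An infeasible constraint
#' combination (e.g. micro-homology longer than the deletion) is an error.
#'
#' @param ref Reference genome (named character vector).
#' @param chrom Chromosome to modify.
#' @param start First deleted base (1-based).
#' @param size Deletion size in bp.
#' @param mh_len Exact micro-homology length to construct.
#' @param insert `"none"`, `"random"`, or `"templated"`.
#' @param insert_len Insert length (templated inserts should be >= 5 bp to be
#'   mappable).
#' @param minus1_base Base forced at position -1 of the anchored junction.
#' @param anchor_side `"five"` (default) or `"three"`.
#' @param gc GC content used for any random fill.
#' @param seed Optional seed.
#' @return List with `ref` (modified genome), `record` (a one-row variant
#'   table) and `truth` (the generative labels).
#' @export
implant_deletion <- function(ref, chrom, start, size, mh_len = 0L,
                             insert = c("none", "random", "templated"),
                             insert_len = 0L, minus1_base = "C",
                             anchor_side = c("five", "three"), gc = 0.5,
                             seed = NULL) {
  insert <- match.arg(insert)
  anchor_side <- match.arg(anchor_side)
  stopifnot(chrom %in% names(ref), minus1_base %in% BASES)
  env <- new.env(parent = emptyenv())
  env$ch <- s2c(ref[[chrom]])
  res <- with_seed(seed,
                   implant_into(env, as.integer(start), as.integer(size),
                                as.integer(mh_len), insert,
                                as.integer(insert_len), minus1_base,
                                anchor_side, gc))
  ref[[chrom]] <- c2s(env$ch)
  record <- data.frame(chrom = chrom, start = res$start, end = res$end,
                       ref_allele = substr(ref[[chrom]], res$start, res$end),
                       alt_allele = res$insert, class = NA_character_,
                       genotype = "manual", subpop = "manual",
                       generations = NA_integer_, fwd = TRUE, rev = TRUE,
                       depth = 30L, stringsAsFactors = FALSE)
  truth <- data.frame(chrom = chrom, start = res$start, end = res$end,
                      deletion_size = size, true_mh_length = mh_len,
                      insert_type = insert, insert_len = nchar(res$insert),
                      origin_start = res$origin$start,
                      origin_end = res$origin$end,
                      origin_strand = res$origin$strand,
                      anchor_side = anchor_side,
                      lesion_anchored = TRUE, minus1_base = minus1_base,
                      stringsAsFactors = FALSE)
  list(ref = ref, record = record, truth = truth)
}

# non-overlapping locus reservation
make_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$starts <- integer(0)
  env$ends <- integer(0)
  env
}

reserve_locus <- function(reg, width, genome_length, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    s0 <- sample.int(genome_length - width, 1L)
    if (!any(s0 <= reg$ends & s0 + width - 1L >= reg$starts)) {
      reg$starts <- c(reg$starts, s0)
      reg$ends <- c(reg$ends, s0 + width - 1L)
      return(s0)
    }
  }
  stop("could not place an event without overlap: the genome is saturated; ",
       "increase genome_length or lower the rates")
}

draw_deletion_size <- function(law) {
  if (identical(law$shape, "uniform")) {
    sample(seq(law$min, law$max), 1L)
  } else {
    sz <- round(exp(stats::runif(1, log(law$min), log(law$max))))
    min(max(sz, law$min), law$max)
  }
}

#' Simulate mutation-accumulation lines
#'
#' Generates a reference genome and, per line, Poisson numbers of SNVs,
#' microsatellite indels and 50-500 bp deletions per generation grown. Events
#' are placed uniformly without overlap; each line accumulates its own events
#' through a single-bottleneck pedigree (no sharing across lines unless
#' `shared_fraction > 0`). Deletion junction features follow the configured
#' laws, all constraints are written into the reference, and every event is
#' emitted in normalised (maximal-5'-conservation) form with passing read
#' flags (depth 30, both strands). Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `reference.fa`,
#'   `variants.tsv`, `truth.tsv` and `lines.tsv` there.
#' @return List with `ref` (genome), `variants` (variant table), `truth`
#'   (per-deletion generative labels), `lines` (line metadata) and `config`.
#' @export
simulate_ma_lines <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  res <- with_seed(config$seed, simulate_ma_lines_impl(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(res$ref, file.path(out_dir, "reference.fa"))
    write_variant_table(res$variants, file.path(out_dir, "variants.tsv"))
    utils::write.table(res$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$lines, file.path(out_dir, "lines.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

simulate_ma_lines_impl <- function(config) {
  gc <- config$gc_content
  chrom <- "chrS"
  env <- new.env(parent = emptyenv())
  env$ch <- rnd_bases(config$genome_length, gc)
  reg <- make_registry()
  margin <- 150L
  variants <- list()
  truth <- list()
  lines <- data.frame(subpop = sprintf("L%03d", seq_len(config$n_lines)),
                      genotype = config$genotype,
                      generations = NA_integer_, stringsAsFactors = FALSE)
  for (li in seq_len(config$n_lines)) {
    gens <- if (is.null(config$generations_per_line)) {
      sample(seq(config$generations_range[1], config$generations_range[2]), 1L)
    } else as.integer(config$generations_per_line)
    lines$generations[li] <- gens
    subpop <- lines$subpop[li]
    counts <- stats::rpois(3L, config$class_rates[c("SNV", "microsatellite_indel",
                                                    "deletion_50_500")] * gens)
    # SNVs
    for (k in seq_len(counts[1])) {
      pos <- reserve_locus(reg, 3L, config$genome_length) + 1L
      refb <- env$ch[pos]
      variants[[length(variants) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = pos, ref_allele = refb,
        alt_allele = pick_other(refb), class = NA_character_,
        genotype = config$genotype, subpop = subpop, generations = gens,
        fwd = TRUE, rev = TRUE, depth = 30L, stringsAsFactors = FALSE)
    }
    # microsatellite indels: write a tract, then delete or insert one unit
    for (k in seq_len(counts[2])) {
      u <- sample(1:4, 1L)
      unit <- rnd_bases(u, gc)
      copies <- sample(5:8, 1L)
      width <- u * copies + 8L
      t0 <- reserve_locus(reg, width, config$genome_length) + 4L
      tract_end <- t0 + u * copies - 1L
      env$ch[t0:tract_end] <- rep(unit, copies)
      # break the repeat phase at both tract boundaries
      if (env$ch[t0 - 1L] == env$ch[t0 + u - 1L]) {
        env$ch[t0 - 1L] <- pick_other(env$ch[t0 + u - 1L])
      }
      if (env$ch[tract_end + 1L] == env$ch[tract_end + 1L - u]) {
        env$ch[tract_end + 1L] <- pick_other(env$ch[tract_end + 1L - u])
      }
      is_del <- sample(c(TRUE, FALSE), 1L)
      if (is_del) {
        s <- t0 + u   # delete the second copy; normalisation shifts it 3'
        variants[[length(variants) + 1L]] <- data.frame(
          chrom = chrom, start = s, end = s + u - 1L,
          ref_allele = c2s(unit), alt_allele = "", class = NA_character_,
          genotype = config$genotype, subpop = subpop, generations = gens,
          fwd = TRUE, rev = TRUE, depth = 30L, stringsAsFactors = FALSE)
      } else {
        s <- t0 + u
        variants[[length(variants) + 1L]] <- data.frame(
          chrom = chrom, start = s, end = s - 1L,
          ref_allele = "", alt_allele = c2s(unit), class = NA_character_,
          genotype = config$genotype, subpop = subpop, generations = gens,
          fwd = TRUE, rev = TRUE, depth = 30L, stringsAsFactors = FALSE)
      }
    }
    # 50-500 bp deletions with constructed junction features
    for (k in seq_len(counts[3])) {
      size <- draw_deletion_size(config$deletion_size_law)
      mh <- min(stats::rgeom(1L, config$mh_length_law$p), config$mh_length_law$cap)
      minus1 <- if (stats::runif(1) < config$minus1_c_bias) "C" else {
        sample(c("A", "G", "T"), 1L)
      }
      anchor_side <- if (config$anchor_randomize && stats::runif(1) < 0.5) {
        "three"
      } else "five"
      ins_type <- "none"; ins_len <- 0L
      if (stats::runif(1) < config$insert_prob) {
        if (stats::runif(1) < config$insert_templated_prob) {
          ins_type <- "templated"
          ins_len <- sample(seq(max(5L, config$insert_len_law[["min"]]),
                                config$insert_len_law[["max"]]), 1L)
        } else {
          ins_type <- "random"
          ins_len <- sample(seq(config$insert_len_law[["min"]],
                                config$insert_len_law[["max"]]), 1L)
        }
      }
      s0 <- reserve_locus(reg, size + 2L * margin, config$genome_length)
      s <- s0 + margin
      res <- implant_into(env, s, size, mh, ins_type, ins_len, minus1,
                          anchor_side, gc)
      variants[[length(variants) + 1L]] <- data.frame(
        chrom = chrom, start = res$start, end = res$end,
        ref_allele = c2s(env$ch[res$start:res$end]),
        alt_allele = res$insert, class = NA_character_,
        genotype = config$genotype, subpop = subpop, generations = gens,
        fwd = TRUE, rev = TRUE, depth = 30L, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        subpop = subpop, chrom = chrom, start = res$start, end = res$end,
        deletion_size = size, true_mh_length = mh, insert_type = ins_type,
        insert_len = nchar(res$insert),
        origin_start = res$origin$start, origin_end = res$origin$end,
        origin_strand = res$origin$strand, anchor_side = anchor_side,
        minus1_base = minus1, stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(variants)) {
    do.call(rbind, variants)
  } else empty_variant_table()
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (config$shared_fraction > 0 && nrow(variants) > 0 && config$n_lines > 1) {
    dup <- which(stats::runif(nrow(variants)) < config$shared_fraction)
    if (length(dup)) {
      copies <- variants[dup, , drop = FALSE]
      copies$subpop <- vapply(copies$subpop, function(sp) {
        sample(setdiff(lines$subpop, sp), 1L)
      }, character(1))
      variants <- rbind(variants, copies)
    }
  }
  rownames(variants) <- NULL
  ref <- stats::setNames(c2s(env$ch), chrom)
  list(ref = ref, variants = variants, truth = truth, lines = lines,
       config = config)
}
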