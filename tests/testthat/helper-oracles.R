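# Independent oracles and fixture builders. Oracles deliberately use direct,
# brute-force formulations so they share no code path with the package.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# longest common suffix of the retained 5' flank and the deleted substring,
# capped at w: a substring-based formulation of junction micro-homology
oracle_mh <- function(ref_str, s, e, w) {
  retained <- substr(ref_str, max(1L, s - w), s - 1L)
  deleted <- substr(ref_str, s, e)
  a <- rev(strsplit(retained, "")[[1]])
  b <- rev(strsplit(deleted, "")[[1]])
  k <- 0L
  while (k < min(length(a), length(b), w) &&
         a[k + 1L] == b[k + 1L] && a[k + 1L] != "N") {
    k <- k + 1L
  }
  k
}

# exhaustive two-strand substring search for an insertion origin: slides the
# probe over every offset of both breakpoint vicinities, comparing base by base
oracle_insertion <- function(ref_str, s, e, insert, min_len = 5L, sw = 40L) {
  if (!nzchar(insert)) return("simple")
  if (nchar(insert) < min_len) return("misc")
  rc <- paste(rev(chartr("ACGTN", "TGCAN",
                         strsplit(insert, "")[[1]])), collapse = "")
  clamp_sub <- function(lo, hi) {
    substr(ref_str, max(1L, lo), min(nchar(ref_str), hi))
  }
  regions <- c(clamp_sub(s - sw, s + sw - 1L), clamp_sub(e - sw + 1L, e + sw))
  L <- nchar(insert)
  for (region in regions) {
    for (off in seq_len(max(0L, nchar(region) - L + 1L))) {
      piece <- substr(region, off, off + L - 1L)
      if (piece == insert || piece == rc) return("templated")
    }
  }
  "misc"
}

# exact Mann-Whitney p by enumeration, with U computed from pairwise
# comparisons rather than ranks
oracle_mw <- function(x, y, alternative) {
  n_x <- length(x); n_y <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  U <- u_of(x, y)
  mu <- n_x * n_y / 2
  combos <- utils::combn(n_x + n_y, n_x)
  Us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  switch(alternative,
         greater = mean(Us >= U),
         less = mean(Us <= U),
         two.sided = mean(abs(Us - mu) >= abs(U - mu)))
}

# a junction context with independent uniform windows; optionally respects
# the normalisation invariant (5' -1 base differs from 3' +1 base)
rand_ctx <- function(w = 10L, deletion_size = 100L, normalized = TRUE) {
  up_lost <- rand_seq(w)
  down_retained <- rand_seq(w)
  while (normalized &&
         substr(up_lost, 1, 1) == substr(down_retained, 1, 1)) {
    down_retained <- paste0(sample(setdiff(BASES4, substr(up_lost, 1, 1)), 1),
                            substr(down_retained, 2, w))
  }
  structure(list(w = as.integer(w), chrom = "synthetic", start = 1000L,
                 end = 1000L + deletion_size - 1L,
                 deletion_size = as.integer(deletion_size),
                 up_retained = rand_seq(w), up_lost = up_lost,
                 down_lost = rand_seq(w), down_retained = down_retained),
            class = "junction_context")
}

# minimal well-formed variant row
toy_row <- function(chrom = "chr1", start, end, ref_allele, alt_allele = "",
                    genotype = "wt", subpop = "L1", generations = 40L,
                    fwd = TRUE, rev = TRUE, depth = 30L, class = NA_character_) {
  data.frame(chrom = chrom, start = start, end = end, ref_allele = ref_allele,
             alt_allele = alt_allele, class = class, genotype = genotype,
             subpop = subpop, generations = generations, fwd = fwd, rev = rev,
             depth = depth, stringsAsFactors = FALSE)
}
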