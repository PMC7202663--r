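# Base-composition profiling of deletion breakpoints: detects bases anchored
# at junctions (e.g. a replication-blocking lesion dictating the first lost
# base) as outliers against the local AT/CG content.

comp_chars <- function(x) chartr("ACGTN", "TGCAN", x)

position_labels <- function(window) {
  c(sprintf("+%d", window:1), sprintf("-%d", 1:window))
}

# one row of junction bases per junction, columns +window..+1, -1..-window
junction_base_rows <- function(tab, ref, window, orientation) {
  del <- which(is_deletion_row(tab))
  rows <- vector("list", 2L * length(del))
  for (k in seq_along(del)) {
    i <- del[k]
    cs <- ref[[tab$chrom[i]]]
    s <- tab$start[i]; e <- tab$end[i]
    up_ret <- s2c(window_str(cs, s - window, s - 1L))    # char 1 = +window
    up_lost <- s2c(window_str(cs, s, s + window - 1L))   # char 1 = -1
    dn_lost <- s2c(window_str(cs, e - window + 1L, e))   # char w = -1
    dn_ret <- s2c(window_str(cs, e + 1L, e + window))    # char 1 = +1
    rows[[2L * k - 1L]] <- c(up_ret, up_lost)
    r3 <- c(rev(dn_ret), rev(dn_lost))
    if (orientation == "mirrored") r3 <- comp_chars(r3)
    rows[[2L * k]] <- r3
  }
  m <- do.call(rbind, rows)
  colnames(m) <- position_labels(window)
  m
}

#' Breakpoint base-composition profile
#'
#' Tallies base frequencies at the positions surrounding every deletion
#' junction, from `+window` (retained, counting away from the junction) to
#' `-window` (lost, counting into the deletion), and normalises each base's
#' per-position frequency to that base's mean frequency across all
#' `2*window` positions — i.e. to the relative AT/CG content around the
#' breakpoints. Each event contributes two junctions (5' and 3').
#'
#' Under the default `mirrored` orientation the 3' junction is read on the
#' reverse-complement strand, so both junctions are read retained-to-lost on
#' their own nascent strand; `top_strand` reads both junctions literally off
#' the reference strand. Both modes are first-class and the result records
#' which was used.
#'
#' @param tab Variant table of normalised events.
#' @param ref Reference genome.
#' @param window Flank width per side (default 100, giving 200 positions).
#' @param orientation `"mirrored"` (default) or `"top_strand"`.
#' @param subset `"all"` deletions (default) or `"with_insert"` only.
#' @param min_coverage Minimum fraction of junctions that must cover a
#'   position (non-N) for it to enter the mean/SD estimates (default 0.9);
#'   low-coverage positions are still reported.
#' @return A `composition_profile` object: matrices `f` (raw frequencies) and
#'   `r` (normalised values), per-base `mu` and `sigma` of `r` across
#'   positions, `coverage`, `n_junctions`, and the mode labels.
#' @export
composition_profile <- function(tab, ref, window = 100L,
                                orientation = c("mirrored", "top_strand"),
                                subset = c("all", "with_insert"),
                                min_coverage = 0.9) {
  orientation <- match.arg(orientation)
  subset <- match.arg(subset)
  tab <- coerce_variant_cols(tab)
  if (subset == "with_insert") {
    tab <- tab[nzchar(tab$alt_allele), , drop = FALSE]
  }
  if (!sum(is_deletion_row(tab))) stop("no junctions left after subsetting")
  M <- junction_base_rows(tab, ref, window, orientation)
  n_junctions <- nrow(M)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(ncol(M)), function(j) {
    tabulate(factor(M[, j], levels = bases), nbins = 4L)
  }, numeric(4))
  dimnames(counts) <- list(bases, colnames(M))
  tot <- colSums(counts)
  f <- sweep(counts, 2L, tot, "/")
  f[, tot == 0] <- NA_real_
  coverage <- tot / n_junctions
  cb <- rowMeans(f, na.rm = TRUE)            # per-base content over all positions
  r <- f / cb
  use <- coverage >= min_coverage
  if (!any(use)) stop("no position meets the coverage minimum")
  mu <- rowMeans(r[, use, drop = FALSE], na.rm = TRUE)
  sigma <- apply(r[, use, drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  structure(list(positions = colnames(M), f = f, r = r, mu = mu,
                 sigma = sigma, coverage = coverage,
                 n_junctions = n_junctions, window = as.integer(window),
                 orientation = orientation, subset = subset,
                 min_coverage = min_coverage),
            class = "composition_profile")
}

#' Flag composition outliers beyond k standard deviations
#'
#' Returns every (base, position) whose normalised value lies more than
#' `k` per-base standard deviations from that base's mean — the points drawn
#' outside the dashed bands on a composition plot.
#'
#' @param profile A `composition_profile`.
#' @param k Band width in SD units (default 3).
#' @return Data.frame with columns `base`, `position`, `r`, `side`
#'   (`"high"`/`"low"`) and `z`, sorted by decreasing excess. Bases with zero
#'   SD yield no flags (with a warning).
#' @export
flag_outliers <- function(profile, k = 3) {
  stopifnot(inherits(profile, "composition_profile"))
  out <- list()
  for (b in rownames(profile$r)) {
    s <- profile$sigma[[b]]
    if (is.na(s) || s == 0) {
      warning("sd is zero for base ", b, "; no flags possible")
      next
    }
    z <- (profile$r[b, ] - profile$mu[[b]]) / s
    hit <- which(!is.na(z) & abs(z) > k)
    if (length(hit)) {
      out[[b]] <- data.frame(base = b, position = profile$positions[hit],
                             r = unname(profile$r[b, hit]),
                             side = ifelse(z[hit] > 0, "high", "low"),
                             z = unname(z[hit]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(base = character(0), position = character(0),
                      r = numeric(0), side = character(0), z = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-abs(res$z)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("breakpoint composition profile: %d junctions, %d positions (+%d..-%d)\n",
              x$n_junctions, length(x$positions), x$window, x$window))
  cat(sprintf("  orientation = %s, subset = %s\n", x$orientation, x$subset))
  cat("  per-base normalised mean (SD):\n")
  for (b in names(x$mu)) {
    cat(sprintf("    %s: %.3f (%.3f)\n", b, x$mu[[b]], x$sigma[[b]]))
  }
  fl <- suppressWarnings(flag_outliers(x))
  cat("  flags beyond 3 SD:", nrow(fl), "\n")
  invisible(x)
}

#' @export
as.data.frame.composition_profile <- function(x, ...) {
  fl <- suppressWarnings(flag_outliers(x))
  flagged <- paste(fl$base, fl$position)
  long <- expand.grid(base = rownames(x$f), position = x$positions,
                      stringsAsFactors = FALSE)
  long$f <- as.vector(x$f)
  long$r <- as.vector(x$r)
  long$coverage <- x$coverage[long$position]
  long$flagged <- paste(long$base, long$position) %in% flagged
  long
}

#' @export
plot.composition_profile <- function(x, k = 3, ...) {
  cols <- c(A = "#1b9e77", C = "#d95f02", G = "#7570b3", T = "#e7298a")
  idx <- seq_along(x$positions)
  graphics::matplot(idx, t(x$r), type = "l", lty = 1, col = cols,
                    xlab = "position relative to junction", ylab = "normalised frequency",
                    xaxt = "n", main = sprintf("breakpoint composition (%s, %s)",
                                               x$orientation, x$subset), ...)
  ticks <- idx[seq(1, length(idx), by = max(1, length(idx) %/% 10))]
  graphics::axis(1, at = ticks, labels = x$positions[ticks], las = 2, cex.axis = 0.7)
  for (b in names(x$mu)) {
    graphics::abline(h = x$mu[[b]] + c(-k, k) * x$sigma[[b]], lty = 2,
                     col = cols[[b]])
  }
  graphics::abline(v = length(idx) / 2 + 0.5, col = "grey40")
  fl <- suppressWarnings(flag_outliers(x, k))
  if (nrow(fl)) {
    graphics::points(match(fl$position, x$positions),
                     fl$r, pch = 19, col = cols[fl$base], cex = 1.2)
  }
  graphics::legend("topleft", legend = names(cols), col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Write a composition profile as long-format TSV
#'
#' Columns: base, position, f (raw frequency), r (normalised), coverage,
#' flagged (beyond 3 SD).
#'
#' @param profile A `composition_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
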