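# Micro-homology and insertion-origin statistics over deletion junction sets.
#
# Heatmap geometry: rows index 5'-breakpoint positions +w..+1, -1..-w and
# columns index 3'-breakpoint positions -w..-1, +1..+w, so the main
# micro-homology diagonal (+k vs -k) runs through the centre. Under maximal
# 5' conservation the (-1, +1) cell is structurally empty (the "white
# square") while (+1, -1) picks up the annotation skew.

pos5_labels <- function(w) c(sprintf("+%d", w:1), sprintf("-%d", 1:w))
pos3_labels <- function(w) c(sprintf("-%d", w:1), sprintf("+%d", 1:w))

# n x 2w character matrices of junction bases; column order matches the labels
ctx_base_matrix <- function(ctxs, side = c("five", "three")) {
  side <- match.arg(side)
  w <- ctxs[[1]]$w
  rows <- vapply(ctxs, function(ctx) {
    if (side == "five") c(s2c(ctx$up_retained), s2c(ctx$up_lost))
    else c(s2c(ctx$down_lost), s2c(ctx$down_retained))
  }, character(2L * w))
  m <- t(rows)
  colnames(m) <- if (side == "five") pos5_labels(w) else pos3_labels(w)
  m
}

#' Micro-homology length at a deletion junction
#'
#' The largest k such that, for every 1 <= i <= k, the base at 5' position +i
#' (retained) equals the base at 3' position -i (lost): i.e. the retained 5'
#' suffix matches the deleted 3' suffix. N never matches. The value is capped
#' at `min(w, deletion_size)` — positions beyond the deletion are not lost
#' bases, so a deletion cannot carry more micro-homology than its own length.
#'
#' @param ctx A `junction_context` from [build_junction_context()] (normalised
#'   event assumed).
#' @return Integer micro-homology length (>= 0).
#' @export
mh_length <- function(ctx) {
  stopifnot(inherits(ctx, "junction_context"))
  a <- s2c(ctx$up_retained)
  b <- s2c(ctx$down_lost)
  cap <- min(ctx$w, ctx$deletion_size)
  k <- 0L
  while (k < cap) {
    x <- a[ctx$w - k]; y <- b[ctx$w - k]
    if (x != y || x == "N") break
    k <- k + 1L
  }
  k
}

new_mh_heatmap <- function(matches, counts, n_events, w, source, n_replicates = 1L) {
  cells <- matches / counts
  cells[counts == 0L] <- NA_real_
  structure(list(cells = cells, matches = matches, counts = counts,
                 n_events = n_events, w = w, source = source,
                 n_replicates = n_replicates),
            class = "mh_heatmap")
}

heatmap_from_matrices <- function(B5, B3, n_events, w, source, n_replicates = 1L) {
  p <- 2L * w
  matches <- matrix(0L, p, p, dimnames = list(colnames(B5), colnames(B3)))
  counts <- matrix(0L, p, p, dimnames = dimnames(matches))
  for (i in seq_len(p)) {
    v5 <- B5[, i]
    ok5 <- v5 != "N"
    for (j in seq_len(p)) {
      v3 <- B3[, j]
      ok <- ok5 & v3 != "N"
      counts[i, j] <- sum(ok)
      matches[i, j] <- sum(v5[ok] == v3[ok])
    }
  }
  new_mh_heatmap(matches, counts, n_events, w, source, n_replicates)
}

#' Micro-homology heatmap over a set of deletion junctions
#'
#' For every deletion, each position of the upstream (5') breakpoint is
#' compared with each position of the downstream (3') breakpoint: identical
#' bases score 1, non-identical 0, and each cell holds the score sum divided
#' by the number of contributing events. Events carrying an N at either
#' position are excluded from that cell's denominator.
#'
#' @param ctxs List of `junction_context` objects sharing the same window.
#' @param w Window width; defaults to the contexts' own width.
#' @return An `mh_heatmap` object: `cells` (fractions), `matches` and `counts`
#'   (per-cell numerators/denominators), `n_events`, `w`.
#' @export
mh_heatmap <- function(ctxs, w = NULL) {
  if (!length(ctxs)) stop("need at least one junction context")
  ws <- vapply(ctxs, `[[`, integer(1), "w")
  if (length(unique(ws)) != 1L) stop("contexts disagree on window width")
  if (!is.null(w) && w != ws[1]) stop("contexts have w = ", ws[1], ", not ", w)
  w <- ws[1]
  heatmap_from_matrices(ctx_base_matrix(ctxs, "five"),
                        ctx_base_matrix(ctxs, "three"),
                        length(ctxs), w, "observed")
}

# one application of the maximal-5'-conservation shift in window space;
# bases sliding in from beyond a window are unknown and become N
reannotate_context <- function(ctx) {
  w <- ctx$w
  repeat {
    b <- substr(ctx$up_lost, 1L, 1L)          # 5' position -1
    cc <- substr(ctx$down_retained, 1L, 1L)   # 3' position +1
    if (b == "N" || b != cc) break
    ctx$up_retained <- paste0(substr(ctx$up_retained, 2L, w), b)
    ctx$up_lost <- paste0(substr(ctx$up_lost, 2L, w), "N")
    ctx$down_lost <- paste0(substr(ctx$down_lost, 2L, w), cc)
    ctx$down_retained <- paste0(substr(ctx$down_retained, 2L, w), "N")
    ctx$start <- ctx$start + 1L
    ctx$end <- ctx$end + 1L
  }
  ctx
}

#' Shuffled-flank null heatmap
#'
#' The reference set against which observed micro-homology is judged: for each
#' replicate and event, each of the four junction windows is independently
#' shuffled preserving its base composition, the implied event is re-annotated
#' under maximal 5' conservation (so the methodological skew of that rule —
#' the empty (-1, +1) cell and the elevated (+1, -1) cell — appears in the
#' null as well), and the heatmap is recomputed. Cells pool matches and
#' denominators over replicates.
#'
#' @param ctxs List of `junction_context` objects.
#' @param w Window width check, as in [mh_heatmap()].
#' @param n_replicates Shuffle replicates (default 10).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return An `mh_heatmap` with `source = "shuffled null"`.
#' @export
shuffled_null <- function(ctxs, w = NULL, n_replicates = 10L, seed = NULL) {
  if (!length(ctxs)) stop("need at least one junction context")
  ws <- vapply(ctxs, `[[`, integer(1), "w")
  if (length(unique(ws)) != 1L) stop("contexts disagree on window width")
  if (!is.null(w) && w != ws[1]) stop("contexts have w = ", ws[1], ", not ", w)
  w <- ws[1]
  p <- 2L * w
  dn <- list(pos5_labels(w), pos3_labels(w))
  matches <- matrix(0L, p, p, dimnames = dn)
  counts <- matrix(0L, p, p, dimnames = dn)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      shuf <- lapply(ctxs, function(ctx) {
        ctx$up_retained <- shuffle_seq(ctx$up_retained)
        ctx$up_lost <- shuffle_seq(ctx$up_lost)
        ctx$down_lost <- shuffle_seq(ctx$down_lost)
        ctx$down_retained <- shuffle_seq(ctx$down_retained)
        reannotate_context(ctx)
      })
      hm <- heatmap_from_matrices(ctx_base_matrix(shuf, "five"),
                                  ctx_base_matrix(shuf, "three"),
                                  length(shuf), w, "replicate")
      matches <- matches + hm$matches
      counts <- counts + hm$counts
    }
  })
  new_mh_heatmap(matches, counts, length(ctxs), w, "shuffled null", n_replicates)
}

#' Chi-square comparison of one heatmap cell against the null
#'
#' 2x2 Pearson chi-square (no continuity correction) on identity yes/no
#' crossed with observed/shuffled counts at the given cell.
#'
#' @param obs,null `mh_heatmap` objects carrying match and event counts.
#' @param cell Length-2 character vector of position labels, e.g.
#'   `c("+1", "-1")`.
#' @param star_p P-value threshold for the `"***"` star annotation
#'   (default 0.001; anything above is `"NS"`).
#' @return List with `statistic`, `p`, `stars`, the 2x2 `table`, and
#'   `applicable` (`FALSE`, with `stars = "inapplicable"`, when a zero margin
#'   makes the test undefined).
#' @export
compare_cell <- function(obs, null, cell = c("+1", "-1"), star_p = 0.001) {
  stopifnot(inherits(obs, "mh_heatmap"), inherits(null, "mh_heatmap"),
            length(cell) == 2L)
  i <- cell[1]; j <- cell[2]
  if (!i %in% rownames(obs$cells) || !j %in% colnames(obs$cells)) {
    stop("no such cell: (", i, ", ", j, ")")
  }
  tbl <- rbind(observed = c(yes = obs$matches[i, j],
                            no = obs$counts[i, j] - obs$matches[i, j]),
               shuffled = c(yes = null$matches[i, j],
                            no = null$counts[i, j] - null$matches[i, j]))
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, stars = "inapplicable",
                table = tbl, applicable = FALSE))
  }
  ct <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value),
       stars = if (ct$p.value < star_p) "***" else "NS",
       table = tbl, applicable = TRUE)
}

insertion_search_regions <- function(chrom_seq, start, end, search_window) {
  sw <- search_window
  c(five = window_str(chrom_seq, start - sw, start + sw - 1L),
    three = window_str(chrom_seq, end - sw + 1L, end + sw))
}

classify_insertion_one <- function(chrom_seq, start, end, insert,
                                   min_len, search_window, max_mismatch) {
  if (!nzchar(insert)) return("simple")
  if (nchar(insert) < min_len) return("misc")
  regions <- insertion_search_regions(chrom_seq, start, end, search_window)
  probes <- c(insert, revcomp(insert))
  hit <- if (max_mismatch == 0) {
    any(vapply(probes, function(p) any(grepl(p, regions, fixed = TRUE)), logical(1)))
  } else {
    any(vapply(probes, function(p) {
      any(agrepl(p, regions, max.distance = max_mismatch, fixed = TRUE))
    }, logical(1)))
  }
  if (hit) "templated" else "misc"
}

#' Classify junction insertions by origin
#'
#' Subdivides deletion events into the three junction categories: `simple`
#' (no inserted sequence), `templated` (insert of at least `min_len` bp whose
#' full sequence, on either strand, occurs within `search_window` bases
#' around either breakpoint — i.e. mappable to its origin in the immediate
#' vicinity), and `misc` (insertions below the size threshold or of unknown
#' origin). The vicinity of each breakpoint spans `search_window` bases on
#' both of its sides, including the deleted sequence adjacent to it.
#'
#' @param tab Variant table (normalised); only deletion rows are classified.
#' @param ref Reference genome.
#' @param min_len Minimum insert size mappable to an origin (default 5 bp).
#' @param search_window Vicinity half-width around each breakpoint
#'   (default 40 bp).
#' @param max_mismatch Allowed mismatches in the origin match (default 0,
#'   exact).
#' @return Character vector, one entry per row: the category for deletion
#'   rows, NA otherwise.
#' @export
classify_insertions <- function(tab, ref, min_len = 5L, search_window = 40L,
                                max_mismatch = 0L) {
  tab <- coerce_variant_cols(tab)
  out <- rep(NA_character_, nrow(tab))
  for (i in which(is_deletion_row(tab))) {
    out[i] <- classify_insertion_one(ref[[tab$chrom[i]]], tab$start[i],
                                     tab$end[i], tab$alt_allele[i],
                                     min_len, search_window, max_mismatch)
  }
  out
}

#' Junction summary: insertion categories and micro-homology spectrum
#'
#' @param tab Variant table (normalised).
#' @param ref Reference genome.
#' @param w Window for micro-homology measurement (default 10).
#' @param min_len,search_window Passed to [classify_insertions()].
#' @return A `junction_summary` list: `fractions` (named, summing to 1 over
#'   simple/templated/misc), `counts`, `mh_hist` (table of micro-homology
#'   lengths), `n_events`.
#' @export
junction_summary <- function(tab, ref, w = 10L, min_len = 5L,
                             search_window = 40L) {
  tab <- coerce_variant_cols(tab)
  del <- which(is_deletion_row(tab))
  if (!length(del)) stop("no deletion events to summarise")
  cats <- classify_insertions(tab, ref, min_len, search_window)[del]
  counts <- c(simple = sum(cats == "simple"),
              templated = sum(cats == "templated"),
              misc = sum(cats == "misc"))
  ctxs <- contexts_from_table(tab, ref, w)
  mh <- vapply(ctxs, mh_length, integer(1))
  out <- list(fractions = counts / length(del), counts = counts,
              mh_hist = table(factor(mh, levels = 0:max(c(mh, 0L)))),
              n_events = length(del))
  class(out) <- "junction_summary"
  out
}

#' @export
print.junction_summary <- function(x, ...) {
  cat("junction summary over", x$n_events, "deletions\n")
  cat(sprintf("  %-10s %5d  (%.1f%%)\n", names(x$counts), x$counts,
              100 * x$fractions), sep = "")
  cat("  micro-homology lengths:\n")
  print(x$mh_hist)
  invisible(x)
}

#' @export
print.mh_heatmap <- function(x, ...) {
  cat(sprintf("micro-homology heatmap (%s): %d events, w = %d%s\n",
              x$source, x$n_events, x$w,
              if (x$n_replicates > 1L) sprintf(", %d replicates", x$n_replicates) else ""))
  centre <- c("+3", "+2", "+1", "-1", "-2", "-3")
  centre_i <- intersect(centre, rownames(x$cells))
  centre_j <- intersect(centre, colnames(x$cells))
  print(round(x$cells[centre_i, centre_j, drop = FALSE], 3))
  cat("(central 6x6 of", nrow(x$cells), "x", ncol(x$cells), "cells shown)\n")
  invisible(x)
}

#' @export
as.matrix.mh_heatmap <- function(x, ...) x$cells

#' @export
plot.mh_heatmap <- function(x, main = NULL, ...) {
  m <- x$cells
  # image() draws row 1 at the bottom; flip so +w is the top row
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z,
                  zlim = c(0, 1), axes = FALSE, xlab = "3' breakpoint position",
                  ylab = "5' breakpoint position",
                  main = if (is.null(main)) sprintf("%s (n = %d)", x$source, x$n_events) else main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2, cex.axis = 0.6)
  graphics::box()
  invisible(x)
}

#' Write a heatmap as a labelled TSV matrix
#'
#' @param hm An `mh_heatmap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(hm, path) {
  utils::write.table(data.frame(pos5 = rownames(hm$cells), hm$cells,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a heatmap as JSON (cells, counts, event count)
#'
#' @param hm An `mh_heatmap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_json <- function(hm, path) {
  jsonlite::write_json(list(source = hm$source, w = hm$w,
                            n_events = hm$n_events,
                            n_replicates = hm$n_replicates,
                            pos5 = rownames(hm$cells),
                            pos3 = colnames(hm$cells),
                            cells = hm$cells, counts = hm$counts),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
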