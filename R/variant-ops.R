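# Allele normalisation, variant classification, junction contexts.

# a deletion event: reference bases lost, possibly with an insert; excludes
# SNVs and balanced multi-base substitutions, which delete nothing net
is_deletion_row <- function(tab) {
  nzchar(tab$ref_allele) &
    nchar(tab$ref_allele) != nchar(tab$alt_allele) &
    !is_structural_row(tab)
}

is_structural_row <- function(tab) {
  !is.na(tab$class) & tab$class %in% STRUCTURAL_TAGS
}

#' Normalise deletions to maximal 5' conservation
#'
#' Applies the right-shifting allele convention: while the first deleted base
#' equals the first retained base after the deletion, the deleted interval is
#' shifted one base toward the 3' end, so shared bases are absorbed by the
#' retained 5' flank. The result is the unique right-most annotation and the
#' operation is idempotent. This is the opposite of VCF left-alignment; see
#' [left_align_deletions()] for the converse.
#'
#' Deletions carrying an inserted sequence are returned unchanged and flagged
#' in the `shift_blocked` column: the shift rule speaks only of reference
#' bases, and moving a junction past an insert would change its meaning.
#'
#' @param tab Variant table (any mix of classes; only pure deletion rows move).
#' @param ref Reference genome from [read_genome()].
#' @return The table with updated `start`/`end`/`ref_allele` plus columns
#'   `shifted_by` (bases moved) and `shift_blocked`.
#' @examples
#' ref <- c(chr1 = "ACCCA")
#' tab <- data.frame(chrom = "chr1", start = 2, end = 3, ref_allele = "CC",
#'                   alt_allele = "", genotype = "wt", subpop = "L1",
#'                   generations = 40)
#' normalize_deletions(tab, ref)$start  # 3
#' @export
normalize_deletions <- function(tab, ref) {
  tab <- coerce_variant_cols(tab)
  check_against_reference(tab, ref)
  tab$shifted_by <- 0L
  tab$shift_blocked <- FALSE
  for (i in seq_len(nrow(tab))) {
    if (!is_deletion_row(tab[i, ])) next
    if (nzchar(tab$alt_allele[i])) {
      tab$shift_blocked[i] <- TRUE
      next
    }
    chrom_seq <- ref[[tab$chrom[i]]]
    L <- nchar(chrom_seq)
    s <- tab$start[i]; e <- tab$end[i]
    obs <- substr(chrom_seq, s, e)
    if (obs != tab$ref_allele[i] && !grepl("N", tab$ref_allele[i])) {
      warning("row ", i, ": ref_allele disagrees with reference; using reference bases")
    }
    while (e + 1L <= L &&
           substr(chrom_seq, s, s) == substr(chrom_seq, e + 1L, e + 1L)) {
      s <- s + 1L; e <- e + 1L
    }
    tab$shifted_by[i] <- s - tab$start[i]
    tab$start[i] <- s; tab$end[i] <- e
    tab$ref_allele[i] <- substr(chrom_seq, s, e)
  }
  tab
}

#' Left-align deletions (VCF convention)
#'
#' Converse of [normalize_deletions()]: while the base just before the
#' deletion equals the last deleted base, shift the interval one base toward
#' the 5' end. Used when exporting to VCF.
#'
#' @inheritParams normalize_deletions
#' @return The table with left-aligned pure-deletion rows.
#' @export
left_align_deletions <- function(tab, ref) {
  tab <- coerce_variant_cols(tab)
  check_against_reference(tab, ref)
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(tab$ref_allele[i]) || nzchar(tab$alt_allele[i]) ||
        is_structural_row(tab[i, ])) next
    chrom_seq <- ref[[tab$chrom[i]]]
    s <- tab$start[i]; e <- tab$end[i]
    while (s - 1L >= 1L &&
           substr(chrom_seq, s - 1L, s - 1L) == substr(chrom_seq, e, e)) {
      s <- s - 1L; e <- e - 1L
    }
    tab$start[i] <- s; tab$end[i] <- e
    tab$ref_allele[i] <- substr(chrom_seq, s, e)
  }
  tab
}

# smallest repeating unit of seq with length <= unit_max, or NULL
repeat_unit <- function(seq, unit_max = 4L) {
  n <- nchar(seq)
  if (n == 0L) return(NULL)
  for (p in seq_len(min(unit_max, n))) {
    if (n %% p == 0L) {
      u <- substr(seq, 1L, p)
      if (strrep(u, n %/% p) == seq) return(u)
    }
  }
  NULL
}

# tandem copies of `unit` in chrom_seq ending just before `at` (left) or
# starting at `at` (right)
count_unit_copies <- function(chrom_seq, unit, at, direction) {
  lu <- nchar(unit)
  n <- 0L
  repeat {
    if (direction == "left") {
      lo <- at - (n + 1L) * lu; hi <- at - n * lu - 1L
    } else {
      lo <- at + n * lu; hi <- at + (n + 1L) * lu - 1L
    }
    if (lo < 1L || hi > nchar(chrom_seq)) break
    if (substr(chrom_seq, lo, hi) != unit) break
    n <- n + 1L
  }
  n
}

in_tracts <- function(chrom, start, end, tracts) {
  if (is.null(tracts) || !nrow(tracts)) return(FALSE)
  any(tracts$chrom == chrom & tracts$start <= start & tracts$end >= end)
}

classify_one <- function(r, ref, repeat_tracts, del_min, del_max,
                         ms_unit_max, ms_min_copies) {
  if (is_structural_row(r)) return("structural")
  nref <- nchar(r$ref_allele); nalt <- nchar(r$alt_allele)
  if (nref == 1L && nalt == 1L) return("SNV")
  # microsatellite: pure indel sitting in (or forming) a short tandem repeat
  if (xor(nref > 0L, nalt > 0L)) {
    indel_seq <- if (nref > 0L) r$ref_allele else r$alt_allele
    if (in_tracts(r$chrom, r$start, max(r$end, r$start), repeat_tracts)) {
      return("microsatellite_indel")
    }
    unit <- repeat_unit(indel_seq, ms_unit_max)
    if (!is.null(unit)) {
      k <- nchar(indel_seq) %/% nchar(unit)
      copies <- k
      if (!is.null(ref) && r$chrom %in% names(ref)) {
        chrom_seq <- ref[[r$chrom]]
        if (nref > 0L) {     # deletion: allele itself lies in the reference
          copies <- k +
            count_unit_copies(chrom_seq, unit, r$start, "left") +
            count_unit_copies(chrom_seq, unit, r$end + 1L, "right")
        } else {             # insertion before `start`
          copies <- k +
            count_unit_copies(chrom_seq, unit, r$start, "left") +
            count_unit_copies(chrom_seq, unit, r$start, "right")
        }
      }
      if (copies >= ms_min_copies) return("microsatellite_indel")
    }
  }
  if (nref >= del_min && nref <= del_max) return("deletion_50_500")
  if (nref == 0L) return("insertion")
  "deletion_other"
}

#' Classify variant records
#'
#' Total classification of each record into one of `SNV`,
#' `microsatellite_indel`, `deletion_50_500`, `deletion_other`, `insertion`,
#' `structural`. Records arriving with a structural tag (`inversion`,
#' `tandem_duplication`, `GCR`, `structural`) in their `class` column keep it
#' as `structural`. A pure indel counts as a microsatellite indel when it lies
#' inside a supplied repeat tract, or — absent a tract set — when its sequence
#' is a whole multiple of a unit of at most `ms_unit_max` bp present in at
#' least `ms_min_copies` tandem copies across the allele and the adjacent
#' reference. Deletions (with or without an insert) of `del_min`-`del_max` bp
#' form the 50-500 bp class central to TMEJ footprint analysis. Multi-base
#' balanced substitutions fall into `deletion_other`.
#'
#' Classification assumes normalised records ([normalize_deletions()]).
#'
#' @param tab Variant table.
#' @param ref Optional reference genome; without it, microsatellite detection
#'   can only use the allele sequence itself.
#' @param repeat_tracts Optional data.frame (`chrom`, `start`, `end`) of known
#'   repeat intervals.
#' @param del_min,del_max Deletion-class size bounds (default 50 and 500 bp).
#' @param ms_unit_max Largest repeat unit considered (default 4 bp).
#' @param ms_min_copies Minimum tandem copies (default 3).
#' @return Character vector of classes, one per row (a partition: classes
#'   always sum to the number of records).
#' @export
classify_variants <- function(tab, ref = NULL, repeat_tracts = NULL,
                              del_min = 50L, del_max = 500L,
                              ms_unit_max = 4L, ms_min_copies = 3L) {
  tab <- coerce_variant_cols(tab)
  vapply(seq_len(nrow(tab)), function(i) {
    classify_one(tab[i, ], ref, repeat_tracts, del_min, del_max,
                 ms_unit_max, ms_min_copies)
  }, character(1))
}

#' Build the four junction windows for a deletion
#'
#' Constructs the `JunctionContext` feeding all junction statistics: four
#' windows of width `w` read off the top strand of the reference around a
#' (normalised) deletion of positions `start..end`.
#'
#' Position convention (`+k` = k-th retained base counting away from the
#' junction, `-k` = k-th lost base counting into the deletion):
#' \describe{
#'   \item{up_retained}{reference `start-w .. start-1`; its last character is
#'     position +1 at the 5' breakpoint.}
#'   \item{up_lost}{reference `start .. start+w-1`; first character is -1 at
#'     the 5' breakpoint.}
#'   \item{down_lost}{reference `end-w+1 .. end`; last character is -1 at the
#'     3' breakpoint.}
#'   \item{down_retained}{reference `end+1 .. end+w`; first character is +1 at
#'     the 3' breakpoint.}
#' }
#' Windows are N-padded beyond contig ends. For deletions shorter than `w` the
#' two lost windows deliberately overlap (and run into retained sequence),
#' consistently with the reference.
#'
#' @param ref Reference genome.
#' @param chrom,start,end Deletion coordinates (1-based inclusive).
#' @param w Window width per side (must be positive).
#' @return An object of class `junction_context`.
#' @export
build_junction_context <- function(ref, chrom, start, end, w = 10L) {
  if (w <= 0L) stop("window width must be positive")
  if (!chrom %in% names(ref)) stop("unknown chromosome: ", sQuote(chrom))
  if (end < start) stop("end < start")
  cs <- ref[[chrom]]
  ctx <- list(w = as.integer(w), chrom = chrom,
              start = as.integer(start), end = as.integer(end),
              deletion_size = as.integer(end - start + 1L),
              up_retained = window_str(cs, start - w, start - 1L),
              up_lost = window_str(cs, start, start + w - 1L),
              down_lost = window_str(cs, end - w + 1L, end),
              down_retained = window_str(cs, end + 1L, end + w))
  class(ctx) <- "junction_context"
  ctx
}

#' @export
print.junction_context <- function(x, ...) {
  cat(sprintf("junction context %s:%d-%d (%d bp deleted), w = %d\n",
              x$chrom, x$start, x$end, x$deletion_size, x$w))
  cat(sprintf("  5'  %s | %s...\n", x$up_retained, x$up_lost))
  cat(sprintf("  3'  ...%s | %s\n", x$down_lost, x$down_retained))
  invisible(x)
}

#' Junction contexts for every deletion row of a table
#'
#' @param tab Variant table (normalised).
#' @param ref Reference genome.
#' @param w Window width per side.
#' @return List of `junction_context` objects, one per deletion row; the
#'   `"rows"` attribute maps them back to table rows.
#' @export
contexts_from_table <- function(tab, ref, w = 10L) {
  idx <- which(is_deletion_row(tab))
  out <- lapply(idx, function(i) {
    build_junction_context(ref, tab$chrom[i], tab$start[i], tab$end[i], w)
  })
  attr(out, "rows") <- idx
  out
}
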