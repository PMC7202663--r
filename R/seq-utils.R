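# Strand-aware sequence primitives shared by every analysis module.
# All coordinates at the interface are 1-based inclusive.

.ALPHABET <- c("A", "C", "G", "T", "N")

s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

c2s <- function(x) paste(x, collapse = "")

check_seq <- function(s, what = "sequence") {
  if (!is.character(s)) stop(what, " must be a character vector")
  s <- toupper(s)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    stop("non-ACGTN character in ", what, ": ", sQuote(s[bad][1L]))
  }
  s
}

#' Evaluate an expression under a private RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not perturb an enclosing simulation.
#' With `seed = NULL` the expression runs under the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Reverse complement
#'
#' Watson-Crick reverse complement over the alphabet A, C, G, T, N
#' (N maps to N). Vectorised over its argument; an involution.
#'
#' @param s Character vector of DNA sequences (case-folded to upper).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("GGGA")  # "TCCC"
#' @export
revcomp <- function(s) {
  s <- check_seq(s)
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(comp, function(x) c2s(rev(s2c(x))), character(1), USE.NAMES = FALSE)
}

#' Composition-preserving sequence shuffle
#'
#' Returns a uniform random permutation of the characters of `s`. The base
#' multiset is exactly preserved. When `seed` is given the result is
#' deterministic and the caller's RNG state is left untouched; otherwise the
#' draw consumes the current RNG stream (so a single upstream `set.seed`
#' governs a whole run).
#'
#' @param s A single sequence string.
#' @param seed Optional integer seed.
#' @return A shuffled sequence of the same length and composition.
#' @export
shuffle_seq <- function(s, seed = NULL) {
  stopifnot(length(s) == 1L)
  s <- check_seq(s)
  ch <- s2c(s)
  if (length(ch) < 2L) return(s)
  with_seed(seed, c2s(ch[sample.int(length(ch))]))
}

#' Read a reference genome from FASTA
#'
#' Loads a (possibly multi-sequence) FASTA into the plain representation used
#' throughout the package: a named character vector of uppercase chromosome
#' strings. Names are truncated at the first whitespace, matching common
#' aligner behaviour.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a reference genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

# N-filled substring of a single chromosome string; lo/hi may fall outside.
window_str <- function(chrom_seq, lo, hi) {
  if (hi < lo) return("")
  L <- nchar(chrom_seq)
  a <- max(lo, 1L)
  b <- min(hi, L)
  core <- if (a <= b) substr(chrom_seq, a, b) else ""
  left_pad <- max(0L, min(hi, 0L) - lo + 1L)
  right_pad <- max(0L, hi - max(lo - 1L, L))
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

#' Extract a reference window around a position
#'
#' Returns the bases `pos - upstream .. pos + downstream` on the top strand,
#' always of length `upstream + downstream + 1`. Positions falling outside the
#' chromosome are filled with `N` and their count reported in the
#' `"n_filled"` attribute; N never scores as an identity match downstream, so
#' junction statistics near contig ends degrade gracefully rather than erroring.
#'
#' @param ref Named character vector as returned by [read_genome()].
#' @param chrom Chromosome name.
#' @param pos 1-based focal position; must lie on the chromosome.
#' @param upstream,downstream Number of bases to include on each side.
#' @return A sequence string with attribute `n_filled`.
#' @export
extract_window <- function(ref, chrom, pos, upstream, downstream) {
  if (!chrom %in% names(ref)) stop("unknown chromosome: ", sQuote(chrom))
  L <- nchar(ref[[chrom]])
  if (pos < 1L || pos > L) stop("position ", pos, " outside ", chrom, " (length ", L, ")")
  if (upstream < 0L || downstream < 0L) stop("window extents must be >= 0")
  lo <- pos - upstream
  hi <- pos + downstream
  out <- window_str(ref[[chrom]], lo, hi)
  attr(out, "n_filled") <- max(0L, 1L - lo) + max(0L, hi - L)
  out
}

#' Scan a sequence for G-quadruplex motifs
#'
#' Finds all maximal, non-overlapping matches of the canonical quadruplex
#' pattern `(G{min_run,} N{1,max_loop}){n_runs-1} G{min_run,}` — by default
#' four runs of three or more guanines separated by loops of 1-7 bases.
#' Minus-strand hits are found by scanning the reverse complement and mapping
#' coordinates back onto the input.
#'
#' @param s A single sequence string.
#' @param min_run Minimum guanine run length (default 3).
#' @param max_loop Maximum loop length between runs (default 7).
#' @param n_runs Number of guanine runs required (default 4).
#' @param both_strands Scan the minus strand too? (default `TRUE`).
#' @return A data.frame with columns `start`, `end` (1-based inclusive, on the
#'   input strand), `strand` and `matched` (the motif as read on its own
#'   strand), sorted by start within strand. Zero rows when nothing matches.
#' @examples
#' scan_g4("GGGAGGGCGGGCGGG")  # the qua1466 site: one hit spanning 1-15
#' @export
scan_g4 <- function(s, min_run = 3, max_loop = 7, n_runs = 4, both_strands = TRUE) {
  stopifnot(length(s) == 1L, min_run >= 1, max_loop >= 1, n_runs >= 1)
  s <- check_seq(s)
  pat <- sprintf("G{%d,}(?:[ACGTN]{1,%d}G{%d,}){%d}",
                 min_run, max_loop, min_run, n_runs - 1L)
  scan1 <- function(x) {
    m <- gregexpr(pat, x, perl = TRUE)[[1]]
    if (m[1] == -1L) {
      return(data.frame(start = integer(0), end = integer(0),
                        matched = character(0), stringsAsFactors = FALSE))
    }
    st <- as.integer(m)
    len <- attr(m, "match.length")
    data.frame(start = st, end = st + len - 1L,
               matched = substring(x, st, st + len - 1L),
               stringsAsFactors = FALSE)
  }
  plus <- scan1(s)
  plus$strand <- rep("+", nrow(plus))
  out <- plus
  if (both_strands) {
    L <- nchar(s)
    rc <- revcomp(s)
    minus <- scan1(rc)
    if (nrow(minus)) {
      minus <- data.frame(start = L - minus$end + 1L,
                          end = L - minus$start + 1L,
                          matched = minus$matched,
                          strand = rep("-", nrow(minus)),
                          stringsAsFactors = FALSE)
      minus <- minus[order(minus$start), , drop = FALSE]
      out <- rbind(plus, minus)
    }
  }
  rownames(out) <- NULL
  out[, c("start", "end", "strand", "matched")]
}

#' Write motif hits as BED
#'
#' Converts 1-based inclusive motif coordinates to the 0-based half-open BED
#' convention and writes a 6-column BED file (name column carries the matched
#' sequence, score is 0).
#'
#' @param hits Data.frame as returned by [scan_g4()].
#' @param chrom Chromosome name to emit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_bed <- function(hits, chrom, path) {
  bed <- data.frame(chrom = rep(chrom, nrow(hits)),
                    start = hits$start - 1L,   # BED is 0-based half-open
                    end = hits$end,
                    name = hits$matched,
                    score = rep(0L, nrow(hits)),
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
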