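# Variant table ingestion: canonical TSV dialect plus a minimal VCF subset.
#
# A variant table is a plain data.frame with 1-based inclusive coordinates:
#   chrom, start, end   -- first/last affected reference base
#   ref_allele          -- deleted/replaced bases ("" for a pure insertion)
#   alt_allele          -- inserted bases ("" for a pure deletion)
#   class (optional), genotype, subpop, generations, fwd, rev, depth
# For a pure insertion (ref_allele == "") the convention is end == start - 1:
# the insert sits immediately before `start`.

MANDATORY_COLS <- c("chrom", "start", "end", "ref_allele", "alt_allele",
                    "genotype", "subpop", "generations")
OPTIONAL_COLS <- c("class", "fwd", "rev", "depth")
STRUCTURAL_TAGS <- c("structural", "inversion", "tandem_duplication", "GCR")

empty_variant_table <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             ref_allele = character(0), alt_allele = character(0),
             class = character(0), genotype = character(0),
             subpop = character(0), generations = integer(0),
             fwd = logical(0), rev = logical(0), depth = integer(0),
             stringsAsFactors = FALSE)
}

# one problem string per row, NA where the row is well-formed
row_problems <- function(df) {
  n <- nrow(df)
  prob <- rep(NA_character_, n)
  note <- function(idx, msg) {
    idx <- which(idx & is.na(prob))
    prob[idx] <<- msg
  }
  note(is.na(df$chrom) | !nzchar(df$chrom), "missing chrom")
  note(is.na(df$start) | is.na(df$end), "non-numeric coordinate")
  alle_bad <- grepl("[^ACGTN]", df$ref_allele) | grepl("[^ACGTN]", df$alt_allele)
  note(alle_bad, "allele outside {A,C,G,T,N}")
  note(!nzchar(df$ref_allele) & !nzchar(df$alt_allele), "both alleles empty")
  has_ref <- nzchar(df$ref_allele)
  note(has_ref & (df$end < df$start), "end < start for non-empty ref_allele")
  note(has_ref & !is.na(df$start) &
         (nchar(df$ref_allele) != df$end - df$start + 1L),
       "ref_allele length != end - start + 1")
  note(!has_ref & !is.na(df$start) & (df$end != df$start - 1L),
       "pure insertion must have end == start - 1")
  note(!is.na(df$generations) & df$generations <= 0, "generations must be positive")
  prob
}

coerce_variant_cols <- function(df) {
  for (cc in OPTIONAL_COLS) if (!cc %in% names(df)) df[[cc]] <- NA
  df$chrom <- as.character(df$chrom)
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  df$ref_allele <- toupper(ifelse(is.na(df$ref_allele), "", as.character(df$ref_allele)))
  df$alt_allele <- toupper(ifelse(is.na(df$alt_allele), "", as.character(df$alt_allele)))
  df$ref_allele[df$ref_allele %in% c(".", "-")] <- ""
  df$alt_allele[df$alt_allele %in% c(".", "-")] <- ""
  df$class <- as.character(df$class)
  df$genotype <- as.character(df$genotype)
  df$subpop <- as.character(df$subpop)
  df$generations <- suppressWarnings(as.integer(df$generations))
  df$fwd <- as.logical(df$fwd)
  df$rev <- as.logical(df$rev)
  df$depth <- suppressWarnings(as.integer(df$depth))
  df[, c(MANDATORY_COLS[1:5], "class", MANDATORY_COLS[6:8], "fwd", "rev", "depth")]
}

check_against_reference <- function(df, ref) {
  unknown <- setdiff(unique(df$chrom), names(ref))
  if (length(unknown)) stop("chromosome(s) not in reference: ",
                            paste(sQuote(unknown), collapse = ", "))
  L <- nchar(ref)[df$chrom]
  bad <- df$start < 1L | pmax(df$end, df$start) > L
  if (any(bad)) {
    stop("coordinate outside reference for row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  invisible(df)
}

#' Read a variant table
#'
#' Reads either the canonical tab-separated dialect (header row required) or a
#' deliberately minimal VCF 4.x subset. Malformed rows are dropped with a
#' warning naming their line numbers and returned in the `"rejected"`
#' attribute; a missing mandatory column is an error. When a reference genome
#' is supplied, coordinates are checked against it and an out-of-range
#' coordinate is an error.
#'
#' The VCF subset maps REF/ALT length differences onto the package's
#' right-anchored allele representation by stripping the shared anchor base:
#' `REF="ATTT", ALT="A"` at position p becomes a deletion of `TTT` starting at
#' p+1. Multi-allelic records and symbolic alleles other than `<DEL>` (with
#' optional `END=` and `INSSEQ=` INFO keys) are rejected. Sample/line metadata
#' may ride along in INFO keys `GENOTYPE`, `SUBPOP`, `GENERATIONS`, `DP`.
#'
#' @param path Path to the input file.
#' @param dialect `"tsv"` (default) or `"vcf_subset"`.
#' @param ref Optional reference genome ([read_genome()]) for coordinate and
#'   allele checks.
#' @return A variant table data.frame (see package overview for columns), with
#'   attribute `rejected` describing any dropped rows.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_subset"), ref = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", check.names = FALSE)
    missing_cols <- setdiff(MANDATORY_COLS, names(df))
    if (length(missing_cols)) {
      stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
    }
    df <- coerce_variant_cols(df)
    lineno <- seq_len(nrow(df)) + 1L   # header is line 1
  } else {
    parsed <- parse_vcf_subset(path, ref)
    df <- parsed$df
    lineno <- parsed$lineno
    pre_rejected <- parsed$rejected
  }
  prob <- row_problems(df)
  rejected <- data.frame(line = lineno[!is.na(prob)],
                         reason = prob[!is.na(prob)],
                         stringsAsFactors = FALSE)
  if (dialect == "vcf_subset" && nrow(pre_rejected)) {
    rejected <- rbind(pre_rejected, rejected)
  }
  if (nrow(rejected)) {
    warning(nrow(rejected), " malformed row(s) dropped (lines ",
            paste(utils::head(rejected$line, 10L), collapse = ", "), ")")
  }
  out <- df[is.na(prob), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(ref) && nrow(out)) check_against_reference(out, ref)
  attr(out, "rejected") <- rejected
  out
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

parse_vcf_subset <- function(path, ref = NULL) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  rejected <- data.frame(line = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  reject <- function(i, why) {
    rejected <<- rbind(rejected, data.frame(line = i, reason = why,
                                            stringsAsFactors = FALSE))
  }
  rows <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) { reject(i, "fewer than 8 VCF fields"); next }
    chrom <- f[1]; pos <- suppressWarnings(as.integer(f[2]))
    ref_a <- toupper(f[4]); alt_a <- toupper(f[5]); info <- f[8]
    if (is.na(pos)) { reject(i, "non-integer POS"); next }
    if (grepl(",", alt_a, fixed = TRUE)) { reject(i, "multi-allelic record"); next }
    if (alt_a == "<DEL>") {
      end <- suppressWarnings(as.integer(info_field(info, "END")))
      if (is.na(end)) { reject(i, "<DEL> without END"); next }
      start <- pos + 1L
      del_seq <- if (!is.null(ref) && chrom %in% names(ref)) {
        substr(ref[[chrom]], start, end)
      } else strrep("N", end - start + 1L)
      ins <- info_field(info, "INSSEQ")
      row <- list(chrom = chrom, start = start, end = end,
                  ref_allele = del_seq,
                  alt_allele = if (is.na(ins)) "" else toupper(ins))
    } else if (grepl("[^ACGTN]", ref_a) || grepl("[^ACGTN]", alt_a)) {
      reject(i, "unsupported symbolic allele"); next
    } else if (nchar(ref_a) == 1L && nchar(alt_a) == 1L) {
      row <- list(chrom = chrom, start = pos, end = pos,
                  ref_allele = ref_a, alt_allele = alt_a)
    } else if (substr(ref_a, 1, 1) == substr(alt_a, 1, 1)) {
      # shared anchor base: strip it; what remains is the deleted/inserted part
      row <- list(chrom = chrom, start = pos + 1L,
                  end = pos + nchar(ref_a) - 1L,
                  ref_allele = substr(ref_a, 2L, nchar(ref_a)),
                  alt_allele = substr(alt_a, 2L, nchar(alt_a)))
    } else {
      row <- list(chrom = chrom, start = pos, end = pos + nchar(ref_a) - 1L,
                  ref_allele = ref_a, alt_allele = alt_a)
    }
    row$class <- NA_character_
    row$genotype <- info_field(info, "GENOTYPE")
    row$subpop <- info_field(info, "SUBPOP")
    row$generations <- suppressWarnings(as.integer(info_field(info, "GENERATIONS")))
    row$fwd <- NA; row$rev <- NA
    row$depth <- suppressWarnings(as.integer(info_field(info, "DP")))
    row$.line <- i
    rows[[k]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(list(df = empty_variant_table(), lineno = integer(0), rejected = rejected))
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  lineno <- df$.line
  df$.line <- NULL
  list(df = coerce_variant_cols(df), lineno = lineno, rejected = rejected)
}

#' Write a variant table as TSV
#'
#' Inverse of [read_variant_table()]'s TSV dialect; `read(write(x))` is the
#' identity on the canonical columns.
#'
#' @param tab Variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write deletion intervals as BED
#'
#' Emits the deletion rows of a variant table as a 0-based half-open BED4
#' (name = genotype:subpop).
#'
#' @param tab Variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deletions_bed <- function(tab, path) {
  keep <- is_deletion_row(tab)
  bed <- data.frame(chrom = tab$chrom[keep],
                    start = tab$start[keep] - 1L,
                    end = tab$end[keep],
                    name = paste0(tab$genotype[keep], ":", tab$subpop[keep]))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a variant table as a minimal VCF
#'
#' Deletions are converted back to the left-aligned, anchor-base VCF
#' convention ([left_align_deletions()]); metadata rides in INFO keys so a
#' write/read round trip preserves the record set.
#'
#' @param tab Variant table.
#' @param ref Reference genome (required for the anchor base).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_subset <- function(tab, ref, path) {
  tab_l <- left_align_deletions(tab, ref)
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  for (i in seq_len(nrow(tab_l))) {
    r <- tab_l[i, ]
    if (nchar(r$ref_allele) == 1L && nchar(r$alt_allele) == 1L) {
      pos <- r$start; REF <- r$ref_allele; ALT <- r$alt_allele
    } else {
      pos <- r$start - 1L
      anchor <- substr(ref[[r$chrom]], pos, pos)
      REF <- paste0(anchor, r$ref_allele)
      ALT <- paste0(anchor, r$alt_allele)
    }
    info <- sprintf("GENOTYPE=%s;SUBPOP=%s;GENERATIONS=%s%s",
                    r$genotype, r$subpop, r$generations,
                    if (!is.na(r$depth)) sprintf(";DP=%d", r$depth) else "")
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                              r$chrom, pos, REF, ALT, info))
  }
  writeLines(lines, path)
  invisible(path)
}
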