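# End-to-end orchestration: one call from variant table + reference to the
# full set of junction-signature, composition and rate outputs, with a
# manifest recording the resolved configuration. Every number written to disk
# is the return value of the corresponding library function; the pipeline
# adds no arithmetic of its own.

#' Run the full deletion-signature analysis
#'
#' Reads (or accepts) a variant table and reference, applies the de novo
#' filter, normalises deletions, classifies variants, and writes: a
#' per-genotype rate table, deletion size distributions, the insertion
#' category summary, the observed micro-homology heatmap with its
#' shuffled-flank null and per-cell chi-square tests, breakpoint composition
#' profiles (all deletions and the with-insert subset), and a JSON manifest
#' with the resolved parameters, seed and input hashes. On any error,
#' partial outputs are removed.
#'
#' @param variants Variant table (data.frame) or path to a TSV in the
#'   canonical dialect.
#' @param ref Reference genome (named character vector) or FASTA path.
#' @param out_dir Output directory (created; must not exist or be empty).
#' @param lines Optional line metadata (`subpop`, `genotype`, `generations`);
#'   derived from the variant table when omitted.
#' @param w Heatmap window per side (default 10).
#' @param comp_window Composition window per side (default 100).
#' @param n_replicates Shuffle replicates for the null (default 10).
#' @param seed Integer seed for the shuffled null (required, so runs are
#'   reproducible).
#' @param orientation Composition orientation mode (default `"mirrored"`).
#' @param min_insert_len,search_window Insertion-origin parameters
#'   (defaults 5 and 40 bp).
#' @param min_depth De novo depth threshold (default 5).
#' @param k_sd Outlier band width in SDs (default 3).
#' @param test_cells Heatmap cells to test against the null (default the
#'   (+1,-1) micro-homology cell).
#' @param apply_filter Apply [filter_de_novo()]? (default `TRUE`).
#' @return Invisibly, a list of the computed objects (`rates`, `sizes`,
#'   `junctions`, `heatmap`, `null`, `cell_tests`, `composition`,
#'   `composition_with_insert`, `manifest`).
#' @export
run_pipeline <- function(variants, ref, out_dir, lines = NULL,
                         w = 10L, comp_window = 100L, n_replicates = 10L,
                         seed, orientation = "mirrored",
                         min_insert_len = 5L, search_window = 40L,
                         min_depth = 5L, k_sd = 3,
                         test_cells = list(c("+1", "-1")),
                         apply_filter = TRUE) {
  if (missing(seed)) stop("a seed is required for a reproducible run")
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  input_files <- character(0)
  tryCatch({
    if (is.character(variants)) {
      input_files <- c(input_files, variants)
      variants <- read_variant_table(variants, "tsv")
    }
    if (is.character(ref) && length(ref) == 1L && file.exists(ref)) {
      input_files <- c(input_files, ref)
      ref <- read_genome(ref)
    }
    variants <- coerce_variant_cols(variants)
    if (apply_filter) {
      flt <- filter_de_novo(variants, min_depth = min_depth)
      kept <- flt$kept
      utils::write.table(flt$rejected, file.path(out_dir, "rejected.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      kept <- variants
    }
    kept <- normalize_deletions(kept, ref)
    kept$class <- ifelse(is_structural_row(kept), "structural",
                         classify_variants(kept, ref))
    if (is.null(lines)) {
      lines <- unique(kept[, c("subpop", "genotype", "generations")])
    }
    rates <- estimate_rates(kept, lines)
    utils::write.table(rates$table, file.path(out_dir, "rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    del <- kept[kept$class %in% c("deletion_50_500", "deletion_other") &
                  nzchar(kept$ref_allele), , drop = FALSE]
    out <- list(rates = rates)
    if (nrow(del)) {
      sizes <- size_distribution(del)
      utils::write.table(sizes$sizes, file.path(out_dir, "sizes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      junctions <- junction_summary(del, ref, w = w,
                                    min_len = min_insert_len,
                                    search_window = search_window)
      jsonlite::write_json(list(fractions = as.list(junctions$fractions),
                                counts = as.list(junctions$counts),
                                n_events = junctions$n_events,
                                mh_hist = as.list(junctions$mh_hist)),
                           file.path(out_dir, "insertion_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      ctxs <- contexts_from_table(del, ref, w = w)
      hm <- mh_heatmap(ctxs)
      null <- shuffled_null(ctxs, n_replicates = n_replicates, seed = seed)
      write_heatmap_tsv(hm, file.path(out_dir, "heatmap_observed.tsv"))
      write_heatmap_tsv(null, file.path(out_dir, "heatmap_null.tsv"))
      cell_tests <- lapply(test_cells, function(cl) {
        ct <- compare_cell(hm, null, cl)
        data.frame(pos5 = cl[1], pos3 = cl[2],
                   obs = hm$cells[cl[1], cl[2]], null = null$cells[cl[1], cl[2]],
                   statistic = ct$statistic, p = ct$p, stars = ct$stars)
      })
      cell_tests <- do.call(rbind, cell_tests)
      utils::write.table(cell_tests, file.path(out_dir, "cell_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      comp <- composition_profile(del, ref, window = comp_window,
                                  orientation = orientation)
      write_composition_tsv(comp, file.path(out_dir, "composition_all.tsv"))
      comp_ins <- NULL
      if (any(nzchar(del$alt_allele))) {
        comp_ins <- composition_profile(del, ref, window = comp_window,
                                        orientation = orientation,
                                        subset = "with_insert")
        write_composition_tsv(comp_ins,
                              file.path(out_dir, "composition_with_insert.tsv"))
      }
      out <- c(out, list(sizes = sizes, junctions = junctions, heatmap = hm,
                         null = null, cell_tests = cell_tests,
                         composition = comp,
                         composition_with_insert = comp_ins))
    }
    manifest <- list(
      package = "tmejsig",
      version = as.character(utils::packageVersion("tmejsig")),
      r_version = R.version.string,
      seed = seed,
      parameters = list(w = w, comp_window = comp_window,
                        n_replicates = n_replicates,
                        orientation = orientation,
                        min_insert_len = min_insert_len,
                        search_window = search_window,
                        min_depth = min_depth, k_sd = k_sd,
                        apply_filter = apply_filter),
      n_input_records = nrow(variants),
      input_md5 = as.list(tools::md5sum(input_files)),
      outputs = c(list.files(out_dir), "manifest.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
    invisible(out)
  }, error = function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    else unlink(list.files(out_dir, full.names = TRUE))
    stop(e)
  })
}
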