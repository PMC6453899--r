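#' Read a feature track
#'
#' Reads bedGraph/BED/wig via [rtracklayer::import()] (or a headered
#' 4-column TSV) into a tidy interval tibble with 0-based half-open
#' coordinates.
#'
#' @param path file path; format inferred from the extension.
#' @param feature optional feature name attached to the rows.
#' @return tibble with `feature`, `chrom`, `start`, `end`, `score`.
#' @export
read_track <- function(path, feature = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("bedgraph", "bg", "bed", "wig", "bw")) {
    gr <- rtracklayer::import(path)
    out <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      score = as.numeric(S4Vectors::mcols(gr)$score)
    )
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = "ciid") %>%
      rlang::set_names(c("chrom", "start", "end", "score"))
  }
  out$feature <- feature %||% tools::file_path_sans_ext(basename(path))
  out %>% select("feature", "chrom", "start", "end", "score")
}

#' Mean feature score in a window around each locus
#'
#' For each locus, the base-weighted mean of the track score over the
#' window `[pos - window/2, pos + window/2)` (0-based half-open): interval
#' scores are expanded to covered bases, positions without data are
#' ignored, and an all-missing window yields a missing score. Loci on
#' chromosomes absent from the track get a missing score with a warning.
#'
#' @param track tibble with `chrom`, `start`, `end`, `score` (one feature).
#' @param loci tibble with `barcode`, `chrom`, `pos`.
#' @param window window size in bp (default 2000).
#' @return tibble with `barcode`, `score`.
#' @export
aggregate_feature_window <- function(track, loci, window = 2000L) {
  half <- window %/% 2L
  missing_chrom <- setdiff(unique(loci$chrom), unique(track$chrom))
  if (length(missing_chrom)) {
    warn(sprintf("no track data on: %s",
                 paste(missing_chrom, collapse = ", ")))
  }
  win <- GenomicRanges::GRanges(
    loci$chrom,
    IRanges::IRanges(start = loci$pos - half + 1L, # 1-based closed
                     end = loci$pos + half))
  tr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(start = track$start + 1L, end = track$end))
  # seqlevel mismatches are handled via the explicit warning above
  suppressWarnings({
    hits <- GenomicRanges::findOverlaps(win, tr)
    ov <- IRanges::pintersect(win[S4Vectors::queryHits(hits)],
                              tr[S4Vectors::subjectHits(hits)])
  })
  dat <- tibble(
    locus = S4Vectors::queryHits(hits),
    width = GenomicRanges::width(ov),
    score = track$score[S4Vectors::subjectHits(hits)]
  ) %>%
    group_by(.data$locus) %>%
    summarise(score = sum(.data$score * .data$width) / sum(.data$width),
              .groups = "drop")
  tibble(barcode = loci$barcode,
         score = dat$score[match(seq_len(nrow(loci)), dat$locus)])
}

#' Correlate per-IR responses with aggregated feature scores
#'
#' Pearson correlation of each response column against each feature, with
#' two-sided t-test p-values and Benjamini-Hochberg adjustment across the
#' full association table (one family per call). Zero-variance features are
#' skipped and logged.
#'
#' @param responses tibble with `barcode` plus one column per response
#'   (e.g. deletion frequency, insertion frequency, expression).
#' @param features long tibble with `barcode`, `feature`, `score`, and
#'   optionally `category`.
#' @param min_n minimal number of complete (response, feature) pairs
#'   (default 10); fewer is an error.
#' @return tibble with `response`, `feature` (and `category` if supplied),
#'   `r`, `n`, `p_value`, `q_value`.
#' @export
correlate_features <- function(responses, features, min_n = 10L) {
  resp_cols <- setdiff(names(responses), "barcode")
  has_cat <- "category" %in% names(features)
  feats <- features %>%
    tidyr::pivot_wider(id_cols = "barcode", names_from = "feature",
                       values_from = "score")
  merged <- inner_join(responses, feats, by = "barcode")
  feat_names <- setdiff(names(feats), "barcode")

  skipped <- character(0)
  rows <- purrr::map(resp_cols, function(rc) {
    purrr::map(feat_names, function(fc) {
      x <- merged[[rc]]
      y <- merged[[fc]]
      ok <- complete.cases(x, y)
      if (sum(ok) < min_n) {
        abort(sprintf("fewer than %d IRs with both %s and %s", min_n, rc, fc))
      }
      if (sd(y[ok]) == 0 || sd(x[ok]) == 0) {
        skipped <<- c(skipped, fc)
        return(NULL)
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson",
                     alternative = "two.sided")
      tibble(response = rc, feature = fc, r = unname(ct$estimate),
             n = sum(ok), p_value = ct$p.value)
    }) %>% purrr::compact() %>% bind_rows()
  }) %>% bind_rows()
  if (length(skipped)) {
    warn(sprintf("skipped zero-variance feature(s): %s",
                 paste(unique(skipped), collapse = ", ")))
  }
  rows <- rows %>% mutate(q_value = p.adjust(.data$p_value, method = "BH"))
  if (has_cat) {
    cat_map <- features %>% distinct(.data$feature, .data$category)
    rows <- rows %>% left_join(cat_map, by = "feature") %>%
      select("response", "feature", "category", "r", "n", "p_value",
             "q_value")
  }
  rows
}
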