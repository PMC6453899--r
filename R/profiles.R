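#' Aggregate molecule calls into per-IR outcome-frequency profiles
#'
#' Computes, per IR and assay, the fraction of molecules in each outcome
#' class, the knock-in and error-based insertion frequencies, and the total
#' mutation frequency (1 - wild-type fraction). IRs whose coverage falls
#' below `min_coverage` in any assay of the comparison set are excluded from
#' every assay, mirroring the shared-IR filter used for pool analyses.
#' Replicates with the same `assay` label are merged by pooling counts.
#'
#' @param calls tibble of UID-collapsed calls carrying at least `barcode`,
#'   `outcome`, `knockin`, and an `assay` label column (add one with
#'   `mutate()` before binding assays together).
#' @param min_coverage minimum molecule count per IR per assay (default 30).
#' @return tibble with one row per (barcode, assay): `coverage`,
#'   `wild_type`, `deletion`, `insertion`, `complex`, `knockin_freq`,
#'   `error_insertion_freq`, `mut_freq`.
#' @export
compute_profiles <- function(calls, min_coverage = 30L) {
  if (nrow(calls) == 0L) {
    warn("empty call set: returning empty profile set")
    return(tibble(barcode = character(), assay = character(),
                  coverage = integer(), wild_type = numeric(),
                  deletion = numeric(), insertion = numeric(),
                  complex = numeric(), knockin_freq = numeric(),
                  error_insertion_freq = numeric(), mut_freq = numeric()))
  }
  if (!"assay" %in% names(calls)) {
    calls <- calls %>% mutate(assay = "assay1")
  }
  counts <- calls %>%
    group_by(.data$barcode, .data$assay) %>%
    summarise(
      coverage = n(),
      n_wt = sum(.data$outcome == "wild_type"),
      n_del = sum(.data$outcome == "deletion"),
      n_ins = sum(.data$outcome == "insertion"),
      n_complex = sum(.data$outcome == "complex"),
      n_ki = sum(.data$outcome == "insertion" & .data$knockin),
      .groups = "drop"
    )
  # exclude IRs under-covered in any assay of the set
  keep <- counts %>%
    group_by(.data$barcode) %>%
    summarise(min_cov = min(.data$coverage),
              n_assays = dplyr::n_distinct(.data$assay), .groups = "drop") %>%
    filter(.data$min_cov >= min_coverage,
           .data$n_assays == dplyr::n_distinct(counts$assay)) %>%
    pull("barcode")
  counts %>%
    filter(.data$barcode %in% keep) %>%
    mutate(
      wild_type = .data$n_wt / .data$coverage,
      deletion = .data$n_del / .data$coverage,
      insertion = .data$n_ins / .data$coverage,
      complex = .data$n_complex / .data$coverage,
      knockin_freq = .data$n_ki / .data$coverage,
      error_insertion_freq = (.data$n_ins - .data$n_ki) / .data$coverage,
      mut_freq = 1 - .data$wild_type
    ) %>%
    select("barcode", "assay", "coverage", "wild_type", "deletion",
           "insertion", "complex", "knockin_freq", "error_insertion_freq",
           "mut_freq")
}

# pull one row per indel from the calls' list-columns
unnest_indels <- function(calls, which = c("deletions", "insertions")) {
  which <- match.arg(which)
  calls %>%
    filter(!purrr::map_lgl(.data[[which]], is.null)) %>%
    select("barcode", "uid", "outcome", dplyr::all_of(which)) %>%
    tidyr::unnest(dplyr::all_of(which))
}

#' Deletion and insertion size spectra
#'
#' Per-size frequency tables over the observed deletion and insertion calls,
#' plus the summary fractions the assays report: deletions smaller than
#' 10 bp and single-nucleotide insertions.
#'
#' @param calls UID-collapsed calls from [call_reads()].
#' @return list with tibbles `deletions` and `insertions` (columns `size`,
#'   `n`, `freq`) and scalars `frac_del_lt10`, `frac_ins_1bp`.
#' @export
size_spectra <- function(calls) {
  del <- unnest_indels(calls %>% filter(.data$outcome == "deletion"),
                       "deletions")
  ins <- unnest_indels(calls %>% filter(.data$outcome == "insertion"),
                       "insertions")
  spec <- function(sizes) {
    if (length(sizes) == 0L) {
      return(tibble(size = integer(), n = integer(), freq = numeric()))
    }
    tibble(size = sizes) %>%
      count(.data$size) %>%
      mutate(freq = .data$n / sum(.data$n))
  }
  list(
    deletions = spec(del$length),
    insertions = spec(ins$length),
    frac_del_lt10 = if (nrow(del)) mean(del$length < 10) else NA_real_,
    frac_ins_1bp = if (nrow(ins)) mean(ins$length == 1) else NA_real_
  )
}

#' Deletion-boundary frequencies at candidate break sites
#'
#' A deletion "neighbors" junction `j|j+1` when one of its boundaries
#' coincides with that junction. Deletions with ambiguous placement are
#' weighted by the fraction of their equivalent placements meeting the
#' criterion: a deletion with `k` equivalent placements of which `m` neighbor
#' the junction contributes `m/k`.
#'
#' @param calls UID-collapsed calls (deletion outcomes are used).
#' @param junctions integer junctions `j` (meaning `j|j+1`) to score;
#'   defaults to the canonical 3|4 and alternative 4|5 sites. Must lie
#'   within the protospacer (0..19).
#' @return tibble with `junction`, `weight` (summed weights), `freq`
#'   (weights over the number of deletions), and `n_deletions`.
#' @export
deletion_boundary_frequencies <- function(calls, junctions = c(3L, 4L)) {
  if (any(junctions < 0L | junctions > 19L)) {
    abort("junctions must lie inside the protospacer (0..19)")
  }
  pam_start <- attr(calls, "pam_start")
  if (is.null(pam_start)) abort("calls must carry the 'pam_start' attribute")
  del <- unnest_indels(calls %>% filter(.data$outcome == "deletion"),
                       "deletions")
  n_del <- nrow(del)
  res <- purrr::map(junctions, function(j) {
    w <- purrr::map2_dbl(del$window, del$length, function(starts, len) {
      if (length(starts) == 0L) return(0)
      # boundaries of placement s: left junction = pam_start - s (bond before
      # the first lost base), right junction = pam_start - (s + len) (bond
      # after the last lost base), in PAM-relative coordinates
      left <- pam_start - starts
      right <- pam_start - (starts + len)
      mean(left == j | right == j)
    })
    tibble(junction = j, weight = sum(w),
           freq = if (n_del) sum(w) / n_del else NA_real_,
           n_deletions = n_del)
  })
  bind_rows(res)
}

#' Distribution of inserted bases among 1-bp insertions
#'
#' Per IR, the fraction of single-nucleotide insertions adding each of
#' A/C/G/T; IRs without any 1-bp insertion are omitted. An assay-level
#' summary pools all 1-bp insertions.
#'
#' @param calls UID-collapsed calls.
#' @return list with `per_ir` (tibble `barcode`, `base`, `n`, `freq`) and
#'   `overall` (tibble `base`, `n`, `freq`, always four rows).
#' @export
insertion_base_distribution <- function(calls) {
  ins <- unnest_indels(calls %>% filter(.data$outcome == "insertion"),
                       "insertions") %>%
    filter(.data$length == 1L)
  per_ir <- ins %>%
    count(.data$barcode, base = .data$seq) %>%
    group_by(.data$barcode) %>%
    mutate(freq = .data$n / sum(.data$n)) %>%
    ungroup()
  overall <- tibble(base = DNA_BASES) %>%
    left_join(ins %>% count(base = .data$seq), by = "base") %>%
    mutate(n = tidyr::replace_na(.data$n, 0L),
           freq = if (nrow(ins)) .data$n / sum(.data$n) else NA_real_)
  list(per_ir = per_ir, overall = overall)
}

#' Normalized reporter expression from barcode counts
#'
#' Expression per IR is the ratio of cDNA to genomic-DNA barcode counts,
#' log2-transformed with a pseudocount of 1 on both numerator and
#' denominator. IRs absent from the gDNA table (or with zero gDNA count)
#' are excluded with a warning.
#'
#' @param cdna_counts tibble with `barcode`, `count` from cDNA sequencing.
#' @param gdna_counts tibble with `barcode`, `count` from gDNA sequencing.
#' @return tibble with `barcode`, `cdna`, `gdna`, `expression`.
#' @export
compute_ir_expression <- function(cdna_counts, gdna_counts) {
  merged <- cdna_counts %>%
    rename(cdna = "count") %>%
    left_join(gdna_counts %>% rename(gdna = "count"), by = "barcode")
  dropped <- merged %>% filter(is.na(.data$gdna) | .data$gdna == 0)
  if (nrow(dropped)) {
    warn(sprintf("%d barcode(s) without usable gDNA counts excluded",
                 nrow(dropped)))
  }
  merged %>%
    filter(!is.na(.data$gdna), .data$gdna > 0) %>%
    mutate(expression = log2((.data$cdna + 1) / (.data$gdna + 1))) %>%
    select("barcode", "cdna", "gdna", "expression")
}
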