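#' Parse amplicon reads into barcode, UID and target sequence
#'
#' The synthetic amplicon layout is `[UID][barcode][promoter index][target
#' region]`, with the UID and barcode carried in the sequence itself (no
#' metadata in read names). Barcodes are matched against the reporter
#' library, exactly by default or within a Hamming-distance tolerance.
#' Reads failing the layout or the lookup are kept with a reason code, so
#' the parse rate and the rejection taxonomy are always reportable.
#'
#' @param reads tibble with columns `read_id`, `seq` (see [read_fastq()]).
#' @param library reporter library tibble (see [generate_reporter_library()]),
#'   needing columns `barcode` and `promoter_index`.
#' @param uid_len UID length in nt (default 16).
#' @param index_len promoter-index length in nt (default 5).
#' @param tolerance maximum Hamming distance for barcode matching (default 0,
#'   exact). Ambiguous best hits are rejected.
#' @param min_target minimum target-region length for a read to be parseable.
#' @return tibble with columns `read_id`, `status` ("ok", "truncated",
#'   "aberrant_barcode"), `barcode`, `uid`, `promoter_index`, `target_seq`.
#'   The attribute `"parse_stats"` carries a one-row tibble with counts and
#'   the parse rate (parsed / total).
#' @export
parse_amplicons <- function(reads, library, uid_len = 16L, index_len = 5L,
                            tolerance = 0L, min_target = 30L) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  bc_len <- unique(nchar(library$barcode))
  if (length(bc_len) != 1L) abort("library barcodes must share one length")
  head_len <- uid_len + bc_len + index_len

  n <- nrow(reads)
  status <- rep("ok", n)
  uid <- substr(reads$seq, 1L, uid_len)
  bc_raw <- substr(reads$seq, uid_len + 1L, uid_len + bc_len)
  idx <- substr(reads$seq, uid_len + bc_len + 1L, head_len)
  target <- substr(reads$seq, head_len + 1L, nchar(reads$seq))

  status[nchar(reads$seq) < head_len + min_target] <- "truncated"

  bc_match <- match_barcodes(bc_raw, library$barcode, tolerance)
  status[status == "ok" & is.na(bc_match)] <- "aberrant_barcode"

  out <- tibble(
    read_id = reads$read_id,
    status = status,
    barcode = ifelse(status == "ok", library$barcode[bc_match], NA_character_),
    uid = ifelse(status == "ok", uid, NA_character_),
    promoter_index = ifelse(status == "ok", idx, NA_character_),
    target_seq = ifelse(status == "ok", target, NA_character_)
  )
  stats <- out %>%
    count(.data$status) %>%
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  stats$total <- n
  stats$parse_rate <- sum(out$status == "ok") / max(n, 1L)
  attr(out, "parse_stats") <- stats
  out
}

# Match observed barcodes against a library, exact or within Hamming
# `tolerance`; ties at the best distance give NA (ambiguous).
match_barcodes <- function(observed, library_barcodes, tolerance = 0L) {
  hit <- match(observed, library_barcodes)
  if (tolerance > 0L) {
    todo <- which(is.na(hit) & !is.na(observed))
    if (length(todo)) {
      lib_mat <- do.call(rbind, strsplit(library_barcodes, ""))
      for (i in todo) {
        obs <- strsplit(observed[i], "")[[1]]
        if (length(obs) != ncol(lib_mat)) next
        d <- rowSums(sweep(lib_mat, 2, obs, FUN = "!="))
        best <- min(d)
        if (best <= tolerance && sum(d == best) == 1L) {
          hit[i] <- which.min(d)
        }
      }
    }
  }
  hit
}

#' Classify the repair outcome of one aligned read
#'
#' Classifies the indels of a semi-global alignment against the wild-type
#' region: zero indels is wild-type (substitutions alone never change the
#' class, since the outcome taxonomy has no substitution category and
#' isolated substitutions are dominated by PCR/sequencing error), exactly one
#' deletion or one insertion gives that class, and two or more separate indel
#' events give "complex". Every indel is annotated with its full placement
#' equivalence window - the set of alternative placements that yield a
#' literally identical mutated sequence. An insertion equal to the ssODN
#' insert marks the read as a knock-in.
#'
#' @param alignment a [align_semi_global()] result of read target region vs
#'   wild-type region (ntDNA view).
#' @param pam_start 1-based index of the first PAM base in the reference.
#' @param ssodn optional ssODN definition as returned by [trip_ssodn()].
#' @return a list with `outcome`, `knockin`, `score`, `deletions`,
#'   `insertions` (tibbles with placement windows), `status`.
#' @export
call_mutation <- function(alignment, pam_start, ssodn = NULL) {
  reference <- gsub("-", "", alignment$aligned_ref, fixed = TRUE)
  # reference here is only the consumed span; reconstruct absolute coords via
  # ref_start; the full reference is not needed beyond windows, which are
  # computed on the consumed span's context. Callers pass whole-region
  # alignments, so the span is the region itself in practice.
  span_ok <- alignment$ref_start <= pam_start - 20L &&
    alignment$ref_end >= pam_start - 1L
  if (!span_ok) {
    return(list(outcome = NA_character_, knockin = FALSE,
                score = alignment$score,
                deletions = NULL, insertions = NULL,
                status = "off_target_fragment"))
  }
  ops <- alignment_ops(alignment)
  indels <- ops[ops$op %in% c("del", "ins"), , drop = FALSE]
  outcome <- if (nrow(indels) == 0L) {
    "wild_type"
  } else if (nrow(indels) == 1L && indels$op[1] == "del") {
    "deletion"
  } else if (nrow(indels) == 1L && indels$op[1] == "ins") {
    "insertion"
  } else {
    "complex"
  }
  full_ref <- attr(alignment, "full_reference") %||% reference
  dels <- indels[indels$op == "del", , drop = FALSE]
  inss <- indels[indels$op == "ins", , drop = FALSE]
  deletions <- if (nrow(dels)) {
    tibble(
      ref_start = dels$ref_start, length = dels$length, seq = dels$seq,
      window = purrr::map2(dels$ref_start, dels$length,
                           ~deletion_window(full_ref, .x, .y))
    )
  }
  insertions <- if (nrow(inss)) {
    tibble(
      after = inss$after, length = inss$length, seq = inss$seq,
      window = purrr::map2(inss$after, inss$seq,
                           ~insertion_window(full_ref, .x, .y))
    )
  }
  knockin <- !is.null(ssodn) && !is.null(insertions) &&
    any(insertions$seq == ssodn$insert)
  list(outcome = outcome, knockin = knockin, score = alignment$score,
       deletions = deletions, insertions = insertions, status = "ok")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All alternative ref_start placements of a deletion that reconstruct the
# same mutated sequence (checked literally on the reference string).
deletion_window <- function(reference, ref_start, len, scan = 32L) {
  mutated <- str_delete(reference, ref_start, len)
  cand <- seq(max(1L, ref_start - scan),
              min(nchar(reference) - len + 1L, ref_start + scan))
  cand[vapply(cand, function(s) {
    identical(str_delete(reference, s, len), mutated)
  }, logical(1))]
}

# All alternative after-indices at which an insertion of the same length
# reproduces the same mutated string (the inserted sequence rotates as the
# placement shifts through a repeat). Placement t is equivalent iff deleting
# `len` characters after t from the mutated string recovers the reference.
insertion_window <- function(reference, after, seq, scan = 32L) {
  mutated <- str_insert(reference, after, seq)
  len <- nchar(seq)
  cand <- seq(max(0L, after - scan), min(nchar(reference), after + scan))
  cand[vapply(cand, function(t) {
    identical(str_delete(mutated, t + 1L, len), reference)
  }, logical(1))]
}

#' Call repair outcomes for a batch of parsed reads
#'
#' Aligns each parsed target sequence against the wild-type target region and
#' classifies the outcome with [call_mutation()]. Identical target sequences
#' are aligned once and the call reused, which makes error-free synthetic
#' data essentially free to call.
#'
#' @param parsed output of [parse_amplicons()] (rows with `status != "ok"`
#'   are dropped).
#' @param library reporter library (provides `target_region`).
#' @param guide a [guide_target()] present in the target region.
#' @param params [alignment_params()].
#' @param ssodn optional [trip_ssodn()] definition for knock-in flagging.
#' @return tibble of calls: `read_id`, `barcode`, `uid`, `outcome`,
#'   `knockin`, `score`, `status`, `descriptor` (compact indel syntax) and
#'   list-columns `deletions`, `insertions`. The ntDNA-view PAM index is
#'   attached as attribute `"pam_start"`.
#' @export
call_reads <- function(parsed, library, guide, params = alignment_params(),
                       ssodn = NULL) {
  ok <- parsed %>% filter(.data$status == "ok")
  region <- unique(library$target_region)
  if (length(region) != 1L) abort("library must share one target region")
  v <- ntdna_view(region, guide)

  seqs <- unique(ok$target_seq)
  calls <- purrr::map(seqs, function(s) {
    q <- if (v$strand == "sense") s else revcomp(s)
    al <- align_semi_global(q, v$seq, params)
    attr(al, "full_reference") <- v$seq
    call_mutation(al, v$pam_start, ssodn)
  })
  names(calls) <- seqs

  rows <- purrr::map(calls, function(cl) {
    tibble(outcome = cl$outcome, knockin = cl$knockin, score = cl$score,
           status = cl$status,
           descriptor = call_descriptor(cl),
           deletions = list(cl$deletions), insertions = list(cl$insertions))
  }) %>% bind_rows()
  rows$target_seq <- seqs

  out <- ok %>%
    select("read_id", "barcode", "uid", "target_seq") %>%
    left_join(rows, by = "target_seq") %>%
    select(-"target_seq")
  attr(out, "pam_start") <- v$pam_start
  attr(out, "ntdna_region") <- v$seq
  out
}

call_descriptor <- function(cl) {
  if (is.na(cl$outcome)) return(NA_character_)
  parts <- character(0)
  if (!is.null(cl$deletions) && nrow(cl$deletions)) {
    parts <- c(parts, sprintf("D[%d:%d:%s]", cl$deletions$ref_start,
                              cl$deletions$length, cl$deletions$seq))
  }
  if (!is.null(cl$insertions) && nrow(cl$insertions)) {
    parts <- c(parts, sprintf("I[%d:%s]", cl$insertions$after,
                              cl$insertions$seq))
  }
  if (isTRUE(cl$knockin)) parts <- c(parts, "KI")
  if (!length(parts)) "WT" else paste(parts, collapse = ";")
}

#' Collapse reads sharing a UID into molecules
#'
#' Reads with the same (barcode, UID) are multiple readings of one DNA
#' molecule; they are collapsed to a single call by majority outcome, with
#' ties broken toward wild-type (then deletion > insertion > complex, for
#' determinism). The representative row for the winning outcome is its most
#' frequent descriptor.
#'
#' @param calls output of [call_reads()].
#' @return tibble of one call per molecule, same columns as the input; the
#'   attribute `"collapse_stats"` reports reads, molecules and the
#'   duplication rate.
#' @export
collapse_uids <- function(calls) {
  priority <- c(wild_type = 1L, deletion = 2L, insertion = 3L, complex = 4L)
  ok <- calls %>% filter(!is.na(.data$outcome))
  if (!anyDuplicated(paste(ok$barcode, ok$uid))) {
    # every molecule read once: collapse is the identity
    attr(ok, "collapse_stats") <- tibble(
      n_reads = nrow(ok), n_molecules = nrow(ok), duplication_rate = 0)
    attr(ok, "pam_start") <- attr(calls, "pam_start")
    attr(ok, "ntdna_region") <- attr(calls, "ntdna_region")
    return(ok)
  }
  collapsed <- ok %>%
    group_by(.data$barcode, .data$uid) %>%
    dplyr::group_modify(function(df, key) {
      tab <- table(df$outcome)
      winners <- names(tab)[tab == max(tab)]
      win <- winners[order(priority[winners])][1]
      sub <- df[df$outcome == win, , drop = FALSE]
      rep_desc <- names(sort(table(sub$descriptor), decreasing = TRUE))[1]
      sub[match(rep_desc, sub$descriptor), , drop = FALSE]
    }) %>%
    ungroup()
  attr(collapsed, "collapse_stats") <- tibble(
    n_reads = nrow(ok), n_molecules = nrow(collapsed),
    duplication_rate = 1 - nrow(collapsed) / max(nrow(ok), 1L))
  attr(collapsed, "pam_start") <- attr(calls, "pam_start")
  attr(collapsed, "ntdna_region") <- attr(calls, "ntdna_region")
  collapsed
}
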