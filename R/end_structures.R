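# --- hairpin geometry -------------------------------------------------------
#
# The modelled DNA end is the PAM-proximal fragment of the duplex after
# cleavage at tDNA junction b and ntDNA junction a (PAM-relative, on the
# ntDNA top strand S). Hairpin ligation seals the bottom-strand 3' terminus
# to the top-strand 5' terminus through a loop, and the molecule is
# sequenced 5'->3' from the bottom strand:
#
#   read(a, b) = revcomp(S[P - b ..]) + loop + S[P - a ..]
#
# where P is the index of the first PAM base and a/b are the ntDNA/tDNA
# junctions. The offset a - b > 0 gives a (a-b)-nt 5' overhang; relative to
# the blunt reference read(3, 3), the overhang bases appear as an apex
# duplication (e.g. (3|4t, 4|5nt) duplicates ntDNA base 4 at the apex),
# while a recessed strand shows an apex loss.

hairpin_read <- function(duplex, pam_start, nt_term, t_term, loop) {
  start_nt <- pam_start - nt_term
  start_t <- pam_start - t_term
  if (start_nt < 1L || start_t < 1L ||
      start_nt > nchar(duplex) || start_t > nchar(duplex)) {
    abort("structure terminus outside the duplex")
  }
  paste0(revcomp(substr(duplex, start_t, nchar(duplex))), loop,
         substr(duplex, start_nt, nchar(duplex)))
}

# C->T conversion of the whole single-stranded hairpin read; each original C
# escapes conversion with probability `failure_rate` (failed bisulfite
# conversion, the dominant substitution noise in hairpin data).
convert_bisulfite <- function(seqs, failure_rate = 0) {
  if (failure_rate == 0) return(gsub("C", "T", seqs, fixed = TRUE))
  vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    cs <- which(chars == "C")
    if (length(cs)) {
      keep <- runif(length(cs)) < failure_rate
      chars[cs[!keep]] <- "T"
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# classify a (t_term, nt_term) pair
structure_class <- function(t_term, nt_term) {
  k <- nt_term - t_term
  dplyr::case_when(
    k == 0 ~ "blunt",
    k > 0 ~ sprintf("%d-nt 5' overhang", k),
    TRUE ~ sprintf("%d-nt 3' overhang", -k)
  )
}

structure_label <- function(t_term, nt_term) {
  sprintf("(%d|%dt, %d|%dnt)", t_term, t_term + 1L, nt_term, nt_term + 1L)
}

#' Enumerate DNA end conformations and their expected hairpin reads
#'
#' Enumerates every (tDNA terminus, ntDNA terminus) pair within the
#' enumeration window around the canonical 3|4 cut, builds each
#' conformation's expected hairpin-capture read (bottom strand up to its
#' terminus, loop, top strand from its terminus: a k-nt 5' overhang appears
#' as a k-base apex duplication, a k-nt 3' overhang with a recessed top
#' strand as a k-base apex loss), and merges conformations whose expected
#' reads are literally identical into degeneracy groups. With
#' `bisulfite = TRUE`, expected reads are fully C->T converted (the form the
#' sequencer sees), which itself merges some otherwise distinct structures.
#'
#' @param duplex ntDNA top-strand sequence containing protospacer + PAM with
#'   enough flanking context.
#' @param pam_start 1-based index of the first PAM base in `duplex`.
#' @param window size in bp of the signature window around the cut
#'   (default 30).
#' @param max_overhang maximal overhang length enumerated (default 14, half
#'   the window).
#' @param loop hairpin loop sequence (excluded from the signature window).
#' @param bisulfite build expected reads in bisulfite-converted space.
#' @return an object of class `end_structure_set`: list with `structures`
#'   (tibble `t_term`, `nt_term`, `label`, `class`, `group_id`,
#'   `signature`, `expected_seq`), `reference` (the blunt expected read),
#'   `duplex`, `pam_start`, `loop`, `window`, `apex` (reference index of the
#'   last base before the loop... the apex centre used for windowing).
#' @export
enumerate_structures <- function(duplex, pam_start, window = 30L,
                                 max_overhang = 14L,
                                 loop = "GCGAAGC", bisulfite = TRUE) {
  if (max_overhang > window / 2) {
    abort("`max_overhang` must not exceed half the window")
  }
  half <- window %/% 2L
  termini <- seq(3L - half, 3L + half)
  # keep termini inside the duplex
  termini <- termini[pam_start - termini >= 1L &
                       pam_start - termini <= nchar(duplex)]
  grid <- tidyr::expand_grid(t_term = termini, nt_term = termini) %>%
    filter(abs(.data$nt_term - .data$t_term) <= max_overhang)
  reads <- purrr::map2_chr(grid$nt_term, grid$t_term, function(a, b) {
    hairpin_read(duplex, pam_start, a, b, loop)
  })
  if (bisulfite) reads <- convert_bisulfite(reads, 0)
  reference <- hairpin_read(duplex, pam_start, 3L, 3L, loop)
  if (bisulfite) reference <- convert_bisulfite(reference, 0)
  # apex: reference index of the centre of the loop
  apex <- nchar(revcomp(substr(duplex, pam_start - 3L, nchar(duplex)))) +
    ceiling(nchar(loop) / 2)

  grid <- grid %>%
    mutate(
      label = structure_label(.data$t_term, .data$nt_term),
      class = structure_class(.data$t_term, .data$nt_term),
      expected_seq = reads,
      signature = vapply(reads, function(r) {
        end_signature(r, reference, apex, window)
      }, character(1), USE.NAMES = FALSE)
    ) %>%
    group_by(.data$expected_seq) %>%
    mutate(group_id = dplyr::cur_group_id()) %>%
    ungroup()

  structure(
    list(structures = grid, reference = reference, duplex = duplex,
         pam_start = pam_start, loop = loop, window = window, apex = apex),
    class = "end_structure_set")
}

#' @export
print.end_structure_set <- function(x, ...) {
  cat(sprintf("<end_structure_set> %d conformations in %d degeneracy groups (window %d bp)\n",
              nrow(x$structures), dplyr::n_distinct(x$structures$group_id),
              x$window))
  invisible(x)
}

# canonical indel signature of a read against the hairpin reference,
# restricted to `window` bp around the apex; substitutions are appended
# after a "|" so they can be masked independently
end_signature <- function(read, reference, apex, window,
                          params = alignment_params()) {
  al <- align_semi_global(read, reference, params)
  ops <- alignment_ops(al)
  sig_ops(ops, apex, window)
}

sig_ops <- function(ops, apex, window) {
  half <- window %/% 2L
  lo <- apex - half
  hi <- apex + half
  pos <- ifelse(ops$op == "ins", ops$after, ops$ref_start)
  op_end <- ifelse(ops$op == "del", ops$ref_start + ops$length - 1L, pos)
  inside <- op_end >= lo & pos <= hi
  keep <- ops[inside, , drop = FALSE]
  pos <- pos[inside]
  ind <- keep$op %in% c("del", "ins")
  indels <- sprintf("%s%d:%s", toupper(substr(keep$op[ind], 1, 1)),
                    pos[ind] - apex, keep$seq[ind])
  subs <- sprintf("S%d:%s>%s", pos[!ind] - apex, keep$seq[!ind],
                  keep$read_base[!ind])
  paste(paste(indels, collapse = ","), paste(subs, collapse = ","),
        sep = "|")
}

#' Extract the end-structure signature of one hairpin read
#'
#' Aligns the read against the blunt hairpin reference and isolates the
#' pattern of changes within the signature window around the apex, applying
#' the quality filters of the original re-analysis: alignments shorter than
#' `min_len` columns, with more than `max_gaps` gap columns, or not spanning
#' `min_span` bp around the target site are rejected with a reason code.
#'
#' @param read read sequence.
#' @param enumeration an [enumerate_structures()] result (provides the
#'   reference, apex and window).
#' @param min_len minimal alignment length in columns (default 50).
#' @param max_gaps maximal number of gap columns (default 5).
#' @param min_span minimal reference span around the apex (default 50).
#' @param params [alignment_params()].
#' @return one-row tibble: `status` ("ok", "short_alignment", "gappy",
#'   "no_span"), `signature` (NA unless ok).
#' @export
extract_end_pattern <- function(read, enumeration, min_len = 50L,
                                max_gaps = 5L, min_span = 50L,
                                params = alignment_params()) {
  al <- align_semi_global(read, enumeration$reference, params)
  if (alignment_length(al) < min_len) {
    return(tibble(status = "short_alignment", signature = NA_character_))
  }
  if (alignment_gap_columns(al) > max_gaps) {
    return(tibble(status = "gappy", signature = NA_character_))
  }
  half_span <- min_span %/% 2L
  if (al$ref_start > enumeration$apex - half_span ||
      al$ref_end < enumeration$apex + half_span) {
    return(tibble(status = "no_span", signature = NA_character_))
  }
  ops <- alignment_ops(al)
  tibble(status = "ok",
         signature = sig_ops(ops, enumeration$apex, enumeration$window))
}

#' Remove substitutions from end-structure signatures
#'
#' Substitutions in hairpin reads show no consistent association with end
#' conformations (they are dominated by failed bisulfite conversion, mostly
#' read as T->C changes), so they are masked before matching to avoid
#' confounding otherwise valid indel patterns. Masking is idempotent and
#' leaves indels untouched.
#'
#' @param signatures character vector of signatures (`indels|subs` syntax).
#' @return list with `signatures` (indel-only) and `stats` (tibble of
#'   substitution types and counts).
#' @export
mask_substitutions <- function(signatures) {
  parts <- stringr::str_split_fixed(signatures, stringr::fixed("|"), 2)
  subs <- parts[, 2]
  subs <- subs[subs != ""]
  sub_types <- if (length(subs)) {
    unlist(strsplit(subs, ",")) %>%
      stringr::str_replace("^S-?\\d+:", "")
  } else character(0)
  stats <- if (length(sub_types)) {
    tibble(type = sub_types) %>% count(.data$type, name = "n")
  } else {
    tibble(type = character(), n = integer())
  }
  list(signatures = paste0(parts[, 1], "|"), stats = stats)
}

#' Match observed signatures to end-structure groups
#'
#' Matches each observed signature exactly against the enumerated structure
#' signatures and tabulates relative frequencies; signatures matching no
#' structure are binned as `"other"`. Structures whose signatures become
#' identical under the chosen matching mode cannot be discerned and are
#' merged into one reporting row with their labels joined - with
#' `mask = TRUE` (default) substitutions are ignored on both sides, which
#' merges conformations that differ from the reference only at substituted
#' positions; with `mask = FALSE` reads carrying substitution noise inside
#' the window fail to match, reproducing the as-is-alignment behaviour of
#' the original analysis.
#'
#' @param observed tibble from rows of [extract_end_pattern()] (only
#'   `status == "ok"` rows are used).
#' @param enumeration an [enumerate_structures()] result.
#' @param mask mask substitutions before matching (default TRUE).
#' @return tibble with `label` (member labels joined with "; "), `class`,
#'   `n_members`, `n`, `freq`, sorted by frequency; the `"other"` row
#'   carries `label` "other".
#' @export
match_and_rank <- function(observed, enumeration, mask = TRUE) {
  obs <- observed %>% filter(.data$status == "ok")
  sigs <- obs$signature
  structures <- enumeration$structures
  key <- structures$signature
  if (mask) {
    sigs <- mask_substitutions(sigs)$signatures
    key <- mask_substitutions(key)$signatures
  }
  groups <- structures %>%
    mutate(match_key = key) %>%
    group_by(.data$match_key) %>%
    summarise(
      label = paste(.data$label, collapse = "; "),
      class = paste(unique(.data$class), collapse = "; "),
      n_members = n(), .groups = "drop")
  hit <- match(sigs, groups$match_key)
  tab <- tibble(match_key = groups$match_key[hit]) %>%
    count(.data$match_key) %>%
    left_join(groups, by = "match_key") %>%
    mutate(label = ifelse(is.na(.data$match_key), "other", .data$label),
           class = ifelse(is.na(.data$match_key), "other", .data$class),
           freq = .data$n / sum(.data$n)) %>%
    select(-"match_key") %>%
    arrange(dplyr::desc(.data$freq))
  tab
}

#' Simulate hairpin-capture reads of DNA end structures
#'
#' Draws reads from a mixture of end conformations: each read is the
#' expected bisulfite-converted hairpin read of its sampled structure, with
#' per-C conversion failures injected at the configured rate (failures keep
#' an original C that should have read as T).
#'
#' @param duplex ntDNA top-strand sequence containing protospacer + PAM.
#' @param pam_start 1-based index of the first PAM base.
#' @param mixture tibble with `t_term`, `nt_term`, `weight` (weights sum
#'   to 1).
#' @param n_reads number of reads.
#' @param config a [simulation_config()] (supplies
#'   `bisulfite_failure_rate` and the seed).
#' @param loop,window,max_overhang as in [enumerate_structures()].
#' @return list with `reads` (tibble `read_id`, `seq`) and `truth` (tibble
#'   `read_id`, `t_term`, `nt_term`, `label`).
#' @export
simulate_hcodes_reads <- function(duplex, pam_start, mixture,
                                  n_reads = 1000L,
                                  config = simulation_config(),
                                  loop = "GCGAAGC", window = 30L,
                                  max_overhang = 14L) {
  if (abs(sum(mixture$weight) - 1) > 1e-8) {
    abort("mixture weights must sum to 1")
  }
  half <- window %/% 2L
  bad <- abs(mixture$nt_term - mixture$t_term) > max_overhang |
    abs(mixture$t_term - 3L) > half | abs(mixture$nt_term - 3L) > half
  if (any(bad)) {
    abort("mixture contains structures outside the enumeration window")
  }
  with_seed(derive_seed(config$seed, 0L, 5L), {
    pick <- sample.int(nrow(mixture), n_reads, replace = TRUE,
                       prob = mixture$weight)
    base_reads <- purrr::map_chr(seq_len(nrow(mixture)), function(i) {
      hairpin_read(duplex, pam_start, mixture$nt_term[i], mixture$t_term[i],
                   loop)
    })
    seqs <- convert_bisulfite(base_reads[pick],
                              config$bisulfite_failure_rate)
    list(
      reads = tibble(read_id = sprintf("hcodes_%06d", seq_len(n_reads)),
                     seq = seqs),
      truth = tibble(read_id = sprintf("hcodes_%06d", seq_len(n_reads)),
                     t_term = mixture$t_term[pick],
                     nt_term = mixture$nt_term[pick],
                     label = structure_label(mixture$t_term[pick],
                                             mixture$nt_term[pick]))
    )
  })
}
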