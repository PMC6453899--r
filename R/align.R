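#' Alignment scoring parameters
#'
#' The semi-global scheme used for amplicon mutation calling: match +2,
#' mismatch -2, gap opening -5, gap extension -0.5 (a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`), plus a constant initial score of 30.
#' The initial score is an additive offset only and never changes the optimal
#' alignment; it is kept so reported scores are comparable with the original
#' scheme.
#'
#' @param match match reward (>= 0).
#' @param mismatch mismatch penalty (<= 0).
#' @param gap_open penalty for the first column of a gap (<= mismatch).
#' @param gap_extend penalty for each further gap column (<= 0).
#' @param initial_score additive score offset.
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -2, gap_open = -5,
                             gap_extend = -0.5, initial_score = 30) {
  if (!(gap_open <= mismatch && mismatch <= 0 && 0 <= match)) {
    abort("require gap_open <= mismatch <= 0 <= match")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, initial_score = initial_score),
            class = "alignment_params")
}

#' Semi-global alignment of a read against a wild-type reference
#'
#' Aligns `query` against `reference` with affine gap costs. "Semi-global"
#' means end gaps in the query (unaligned reference flanks) are free, because
#' reads span a fixed PCR amplicon and reference overhangs reflect layout,
#' not biology; the query itself is fully aligned. `N` matches nothing and is
#' scored as a mismatch. Traceback is deterministic and indels are normalised
#' to their 3'-most equivalent placement (the convention deterministic
#' variant callers use when an insertion repeats its neighbour).
#'
#' @param query read sequence (ACGTN).
#' @param reference wild-type sequence (ACGTN).
#' @param params an [alignment_params()].
#' @return an object of class `semiglobal_alignment`: a list with `score`
#'   (including the initial-score offset), `aligned_query`, `aligned_ref`
#'   (gapped strings), `ref_start`/`ref_end` (1-based consumed reference
#'   span) and `params`.
#' @export
align_semi_global <- function(query, reference, params = alignment_params()) {
  assert_dna(query, arg = "query")
  assert_dna(reference, arg = "reference")
  res <- .semiglobal_align_cpp(query, reference,
                               params$match, params$mismatch,
                               abs(params$gap_open), abs(params$gap_extend))
  res <- normalise_indels_3prime(res)
  structure(
    list(score = res$score + params$initial_score,
         aligned_query = res$aligned_query,
         aligned_ref = res$aligned_ref,
         ref_start = res$ref_start, ref_end = res$ref_end,
         params = params),
    class = "semiglobal_alignment"
  )
}

#' @export
print.semiglobal_alignment <- function(x, ...) {
  cat(sprintf("<semiglobal_alignment> score %.1f, reference span %d-%d\n",
              x$score, x$ref_start, x$ref_end))
  cat(" ", x$aligned_ref, "\n ", x$aligned_query, "\n")
  invisible(x)
}

# Shift every gap run to its 3'-most (rightmost) equivalent placement.
# Operates on the gapped strings; score-neutral by construction.
normalise_indels_3prime <- function(res) {
  aq <- strsplit(res$aligned_query, "")[[1]]
  ar <- strsplit(res$aligned_ref, "")[[1]]
  L <- length(aq)
  shift_runs <- function(gapped, other) {
    # gapped: the vector containing '-' runs to shift right within `other`
    repeat {
      moved <- FALSE
      i <- 1L
      while (i <= L) {
        if (gapped[i] == "-") {
          j <- i
          while (j < L && gapped[j + 1L] == "-") j <- j + 1L
          # run [i..j]; can shift right if next column is aligned in both and
          # other[i] == other[j+1] (deleting/inserting the same base)
          while (j < L && gapped[j + 1L] != "-" && other[j + 1L] != "-" &&
                 other[i] == other[j + 1L]) {
            gapped[i] <- gapped[j + 1L]
            gapped[j + 1L] <- "-"
            i <- i + 1L
            j <- j + 1L
            moved <- TRUE
          }
          i <- j + 1L
        } else {
          i <- i + 1L
        }
      }
      if (!moved) break
    }
    gapped
  }
  # deletions: gaps in query, shifted along the reference; the reference is
  # ungapped across the run so `other` = ar
  aq <- shift_runs(aq, ar)
  # insertions: gaps in reference, shifted along the query
  ar <- shift_runs(ar, aq)
  res$aligned_query <- paste(aq, collapse = "")
  res$aligned_ref <- paste(ar, collapse = "")
  res
}

#' Extract alignment operations
#'
#' Walks the gapped alignment and reports indels and substitutions in
#' reference coordinates. Deletions carry the lost reference sequence and the
#' 1-based reference start of the run; insertions carry the inserted sequence
#' and the reference index after which they occur (`after`, 0 = before the
#' first base).
#'
#' @param alignment a [align_semi_global()] result.
#' @return tibble with columns `op` ("del", "ins", "sub"), `ref_start`,
#'   `after`, `length`, `seq`, `read_base`.
#' @export
alignment_ops <- function(alignment) {
  aq <- strsplit(alignment$aligned_query, "")[[1]]
  ar <- strsplit(alignment$aligned_ref, "")[[1]]
  L <- length(aq)
  ref_pos <- alignment$ref_start - 1L # last consumed reference index
  ops <- list()
  i <- 1L
  while (i <= L) {
    if (aq[i] == "-") { # deletion from the query: reference bases lost
      j <- i
      while (j < L && aq[j + 1L] == "-") j <- j + 1L
      ops[[length(ops) + 1L]] <- tibble(
        op = "del", ref_start = ref_pos + 1L, after = NA_integer_,
        length = j - i + 1L,
        seq = paste(ar[i:j], collapse = ""), read_base = NA_character_)
      ref_pos <- ref_pos + (j - i + 1L)
      i <- j + 1L
    } else if (ar[i] == "-") { # insertion relative to the reference
      j <- i
      while (j < L && ar[j + 1L] == "-") j <- j + 1L
      ops[[length(ops) + 1L]] <- tibble(
        op = "ins", ref_start = NA_integer_, after = ref_pos,
        length = j - i + 1L,
        seq = paste(aq[i:j], collapse = ""), read_base = NA_character_)
      i <- j + 1L
    } else {
      ref_pos <- ref_pos + 1L
      if (aq[i] != ar[i]) {
        ops[[length(ops) + 1L]] <- tibble(
          op = "sub", ref_start = ref_pos, after = NA_integer_,
          length = 1L, seq = ar[i], read_base = aq[i])
      }
      i <- i + 1L
    }
  }
  if (length(ops) == 0L) {
    tibble(op = character(), ref_start = integer(), after = integer(),
           length = integer(), seq = character(), read_base = character())
  } else {
    bind_rows(ops)
  }
}

# number of gap columns (BLAST-style "gaps") in an alignment
alignment_gap_columns <- function(alignment) {
  sum(strsplit(alignment$aligned_query, "")[[1]] == "-") +
    sum(strsplit(alignment$aligned_ref, "")[[1]] == "-")
}

# number of alignment columns
alignment_length <- function(alignment) {
  nchar(alignment$aligned_query)
}
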