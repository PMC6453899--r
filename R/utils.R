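DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] accepting and returning
#' plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_chars <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

assert_dna <- function(x, allow_n = TRUE, arg = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    abort(sprintf("`%s` must be a single non-empty string", arg))
  }
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, x)) {
    abort(sprintf("`%s` contains symbols outside %s", arg,
                  if (allow_n) "ACGTN" else "ACGT"))
  }
  invisible(x)
}

# Deterministic derivation of per-unit child seeds from a root seed, so that
# adding a unit does not perturb the streams of the others. Kept below 2^31.
derive_seed <- function(root, index, salt = 0L) {
  (as.integer(root) %% 1000003L) * 2011L + as.integer(index) * 7919L +
    as.integer(salt) * 104729L
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

str_insert <- function(x, after, what) {
  # insert `what` after character position `after` (0 = before first char)
  paste0(substr(x, 1L, after), what, substr(x, after + 1L, nchar(x)))
}

str_delete <- function(x, start, len) {
  paste0(substr(x, 1L, start - 1L), substr(x, start + len, nchar(x)))
}

#' Read a FASTQ file into a tibble
#'
#' @param path path to a plain or gzipped FASTQ file.
#' @return a tibble with columns `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(ss), seq = as.character(ss))
}

#' Write reads to a 4-line FASTQ file
#'
#' Quality is constant ("I"); read names carry no metadata (barcode and UID
#' live in the sequence, as in the amplicon design).
#'
#' @param reads tibble with columns `read_id`, `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  readr::write_lines(lines, path)
  invisible(path)
}
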