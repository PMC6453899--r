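#' Define a Cas9 guide target
#'
#' A guide target couples a 20-nt protospacer with its NGG PAM and fixes the
#' coordinate system used throughout the package: positions are counted
#' 1-based upstream of the PAM on the non-target strand (ntDNA, the strand
#' that carries protospacer + PAM read 5'->3'), position 1 abutting the PAM.
#' Junction `j|j+1` is the phosphodiester bond between positions `j` and
#' `j+1`; `3|4` is the canonical blunt cut site and ntDNA "nucleotide 4" the
#' template base duplicated by fill-in of a 1-nt 5' overhang with termini
#' 3|4 (tDNA) and 4|5 (ntDNA).
#'
#' @param protospacer 20-nt protospacer sequence (ntDNA view, 5'->3').
#' @param pam 3-nt PAM, must match NGG.
#' @param name guide label.
#' @param f_staggered fraction of cleavage events producing a 1-nt 5' overhang
#'   (used as the simulation default for this guide), in `[0, 1]`.
#' @return an object of class `guide_target`.
#' @export
guide_target <- function(protospacer, pam, name = "sgRNA",
                         f_staggered = 0.5) {
  assert_dna(protospacer, allow_n = FALSE, arg = "protospacer")
  assert_dna(pam, allow_n = FALSE, arg = "pam")
  if (nchar(protospacer) != 20L) abort("`protospacer` must be 20 nt")
  if (!grepl("^[ACGT]GG$", pam)) abort("`pam` must match NGG")
  if (!is.numeric(f_staggered) || f_staggered < 0 || f_staggered > 1) {
    abort("`f_staggered` must be in [0, 1]")
  }
  structure(
    list(protospacer = protospacer, pam = pam, name = name,
         f_staggered = f_staggered),
    class = "guide_target"
  )
}

#' @export
print.guide_target <- function(x, ...) {
  cat(sprintf("<guide_target> %s: %s|%s (base4 = %s, f_staggered = %.2f)\n",
              x$name, x$protospacer, x$pam, guide_base4(x), x$f_staggered))
  invisible(x)
}

#' The ntDNA base at position 4 upstream of the PAM
#'
#' @param guide a [guide_target()].
#' @return single character, one of A/C/G/T.
#' @export
guide_base4 <- function(guide) {
  substr(guide$protospacer, 17L, 17L)
}

# Locate a guide inside a reference region and return the ntDNA view.
# The ntDNA view is the strand (as given, or reverse complement) on which
# protospacer + PAM read 5'->3'. `pam_start` is the 1-based index of the
# first PAM base in that view.
ntdna_view <- function(region, guide) {
  site <- paste0(guide$protospacer, guide$pam)
  find_once <- function(seqc) {
    hits <- gregexpr(site, seqc, fixed = TRUE)[[1]]
    if (identical(as.integer(hits), -1L)) integer(0) else as.integer(hits)
  }
  fwd <- find_once(region)
  rev <- find_once(revcomp(region))
  if (length(fwd) + length(rev) != 1L) {
    abort(sprintf(
      "guide %s: protospacer+PAM must occur exactly once in the region (found %d)",
      guide$name, length(fwd) + length(rev)))
  }
  if (length(fwd) == 1L) {
    list(seq = region, pam_start = fwd + 20L, strand = "sense")
  } else {
    rc <- revcomp(region)
    list(seq = rc, pam_start = rev + 20L, strand = "antisense")
  }
}

# PAM-relative junction <-> absolute "after-index" conversion in an ntDNA view.
# An insertion "after index t" (0 = before the first base) sits at junction
# j = pam_start - t - 1.
junction_from_after <- function(after, pam_start) pam_start - after - 1L
after_from_junction <- function(junction, pam_start) pam_start - junction - 1L

# ntDNA base at PAM-relative position k (k >= 1 upstream; k <= 0 runs into
# the PAM: position 0 is the PAM N base).
ntdna_base_at <- function(view_seq, pam_start, k) {
  idx <- pam_start - k
  if (idx < 1L || idx > nchar(view_seq)) return(NA_character_)
  substr(view_seq, idx, idx)
}

#' Bundled synthetic guides
#'
#' Three synthetic stand-ins for the study-style guides. They are not the
#' laboratory sequences (those live in supplementary material not bundled
#' here) but share the properties the analysis exercises: sgRNA1 carries a
#' CGGCGG repeat at positions 1-6 upstream of the PAM (the microhomology
#' deletion scenario) with ntDNA base 4 = G and 75% GC; sgRNA2 has base 4 = G
#' and 70% GC; sgRNA3 has base 4 = T and 45% GC. Default `f_staggered` values
#' (0.52, 0.65, 0.97) are back-computed from the dominant 1-bp insertion
#' shares the assays report (63.7%, 73.9%, 97.9%) via
#' `share = f + (1 - f) / 4`.
#'
#' @return a named list of [guide_target()] objects.
#' @export
trip_guides <- function() {
  list(
    sgRNA1 = guide_target("GCCGTGGAGCACTTCGGCGG", "TGG", "sgRNA1",
                          f_staggered = 0.52),
    sgRNA2 = guide_target("CACCGGCTCCAGCGTTGACC", "AGG", "sgRNA2",
                          f_staggered = 0.65),
    sgRNA3 = guide_target("GTACATTGAGCTACAGTCAG", "CGG", "sgRNA3",
                          f_staggered = 0.97)
  )
}

#' Synthetic reporter cassette
#'
#' The wild-type amplicon target region shared by every integrated reporter:
#' a synthetic stand-in for the reporter gene body containing each bundled
#' guide's protospacer + PAM exactly once.
#'
#' @return a single DNA string.
#' @export
trip_cassette <- function() {
  g <- trip_guides()
  cassette <- paste0(
    "ATTCGAACTGGTCATAGC",
    g$sgRNA1$protospacer, g$sgRNA1$pam,
    "TCAATCGA",
    g$sgRNA2$protospacer, g$sgRNA2$pam,
    "AGTTCACT",
    g$sgRNA3$protospacer, g$sgRNA3$pam,
    "CTGAAGTCCAGTTAGCATCCGATTAACGTA"
  )
  cassette
}

#' Synthetic ssODN repair template
#'
#' A 141-nt single-stranded repair template for knock-in at the sgRNA2 cut
#' site of the bundled cassette: a 21-nt insert flanked by 58- and 62-nt
#' homology arms, with the arm junction at the cut site (< 10 bp away).
#'
#' @return a list with elements `template`, `insert`, `arm5`, `arm3`.
#' @export
trip_ssodn <- function() {
  cassette <- trip_cassette()
  g <- trip_guides()$sgRNA2
  v <- ntdna_view(cassette, g)
  cut_after <- after_from_junction(3L, v$pam_start) # blunt cut 3|4
  insert <- "GAATTCGGATCCACGCGTAAC"
  arm5 <- substr(cassette, cut_after - 58L + 1L, cut_after)
  arm3 <- substr(cassette, cut_after + 1L, cut_after + 62L)
  list(template = paste0(arm5, insert, arm3), insert = insert,
       arm5 = arm5, arm3 = arm3, cut_after = cut_after)
}
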