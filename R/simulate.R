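# Seed-scoped evaluation: runs `code` under set.seed(seed) and restores the
# caller's RNG state, so generators never perturb each other.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' The stated world of the synthetic generator: per-locus mutation
#' propensities drawn from a Beta distribution, guide-specific efficiency
#' multipliers, a repair-outcome mixture, negative-binomial coverage and
#' i.i.d. substitution sequencing error. Defaults encode the assay-scale
#' conditions the analyses assume: Beta(2, 2) locus propensities (broad
#' locus-driven spread), guide multipliers (1, 1.04, 1.3) matching the
#' reported 1.30/1.26-fold efficiency gaps, an outcome mixture dominated by
#' deletions (0.78 deletion, 0.12 insertion, 0.10 complex of mutated
#' molecules), knock-in probability 0.06 per mutated molecule when an ssODN
#' is supplied, truncated-geometric deletion sizes on 1..30 bp with
#' `p = 0.14` (so roughly three quarters of deletions are under 10 bp), 90%
#' of insertions being single-nucleotide, mean coverage 100 per reporter,
#' and 0.1% per-base substitution error.
#'
#' @param seed integer root seed; every derived stream is a deterministic
#'   function of it.
#' @param n_irs number of integrated reporters (IRs).
#' @param promoters named numeric vector of promoter mixing weights.
#' @param barcode_len barcode length (16 for the clonal line, 18 for pools).
#' @param propensity_shape `c(a, b)` of the per-IR Beta propensity.
#' @param guide_efficiency named multipliers applied to the propensity.
#' @param f_staggered optional named override of per-guide staggered-end
#'   fractions; defaults to each guide's own value.
#' @param p_deletion,p_insertion,complex_prob outcome mixture given a
#'   mutation (normalised internally).
#' @param knockin_prob probability a mutated molecule integrates the ssODN
#'   insert, when an ssODN is present.
#' @param deletion_geom_p,deletion_max truncated-geometric deletion-size law.
#' @param mh_spike optional `list(triplet=, prob=)` microhomology spike: with
#'   the given probability a deletion removes that triplet just upstream of
#'   the PAM (mimicking MMEJ loss between triplet repeats).
#' @param ins1_prob probability an error insertion is 1 bp.
#' @param coverage_mean,coverage_size negative-binomial coverage per IR.
#' @param seq_error_rate per-base substitution probability.
#' @param bisulfite_failure_rate per-C probability of failed conversion in
#'   hairpin reads.
#' @param uid_len UID length.
#' @return an object of class `cas9_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_irs = 36L,
                              promoters = c(PGK = 1),
                              barcode_len = 16L,
                              propensity_shape = c(a = 2, b = 2),
                              guide_efficiency = c(sgRNA1 = 1, sgRNA2 = 1.04,
                                                   sgRNA3 = 1.3),
                              f_staggered = NULL,
                              p_deletion = 0.78,
                              p_insertion = 0.12,
                              complex_prob = 0.10,
                              knockin_prob = 0.06,
                              deletion_geom_p = 0.14,
                              deletion_max = 30L,
                              mh_spike = NULL,
                              ins1_prob = 0.9,
                              coverage_mean = 100,
                              coverage_size = 10,
                              seq_error_rate = 0.001,
                              bisulfite_failure_rate = 0.05,
                              uid_len = 16L) {
  probs <- c(p_deletion = p_deletion, p_insertion = p_insertion,
             complex_prob = complex_prob, knockin_prob = knockin_prob,
             ins1_prob = ins1_prob, seq_error_rate = seq_error_rate,
             bisulfite_failure_rate = bisulfite_failure_rate)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (!is.null(f_staggered) &&
      any(f_staggered < 0 | f_staggered > 1)) {
    abort("`f_staggered` values must lie in [0, 1]")
  }
  if (coverage_mean <= 0) abort("`coverage_mean` must be > 0")
  if (n_irs < 0) abort("`n_irs` must be non-negative")
  if (any(promoters < 0) || sum(promoters) <= 0 || is.null(names(promoters))) {
    abort("`promoters` must be a named vector of non-negative weights")
  }
  if (!is.null(mh_spike) &&
      (!is.list(mh_spike) || is.null(mh_spike$triplet) ||
       mh_spike$prob < 0 || mh_spike$prob > 1)) {
    abort("`mh_spike` must be list(triplet=, prob in [0,1])")
  }
  structure(as.list(environment()), class = "cas9_sim_config")
}

#' Promoter weights of the multi-promoter pool design
#'
#' Seven promoters mixed at molar ratios 2:2:4:2:2:2:1.
#' @return named numeric vector of weights.
#' @export
trip_pool_promoters <- function() {
  c(CMV = 2, cMyc = 2, Hoxb1 = 4, Nanog = 2, Oct4 = 2, p53 = 2, PGK = 1)
}

promoter_index_codes <- function(promoters) {
  fixed <- c(PGK = "ACGTA", CMV = "CATGC", cMyc = "GTACG", Hoxb1 = "TGCAT",
             Nanog = "CGATC", Oct4 = "ATCGA", p53 = "GCTAG")
  codes <- fixed[promoters]
  missing <- is.na(codes)
  if (any(missing)) {
    # deterministic fallback codes for unknown promoter labels
    pool <- apply(expand.grid(rep(list(DNA_BASES), 5))[, 5:1], 1, paste,
                  collapse = "")
    pool <- setdiff(pool, fixed)
    codes[missing] <- pool[seq_len(sum(missing))]
  }
  names(codes) <- promoters
  codes
}

#' Generate a barcoded reporter library
#'
#' Draws `n_irs` reporter constructs: unique random barcodes, promoters by
#' weight, collision-free genomic loci, and a per-IR mutation propensity from
#' the configured Beta distribution (the locus effect, held constant across
#' assays). All constructs share the synthetic reporter cassette as their
#' wild-type target region.
#'
#' @param config a [simulation_config()].
#' @return tibble with one row per IR: `barcode`, `promoter`,
#'   `promoter_index`, `chrom`, `pos`, `strand`, `mut_propensity`,
#'   `target_region`.
#' @export
generate_reporter_library <- function(config) {
  if (config$n_irs < 1L) abort("`n_irs` must be >= 1")
  cassette <- trip_cassette()
  with_seed(derive_seed(config$seed, 0L, 1L), {
    n <- config$n_irs
    barcodes <- character(0)
    for (round in 1:100) {
      barcodes <- unique(c(barcodes, random_dna(n, config$barcode_len)))
      if (length(barcodes) >= n) break
    }
    if (length(barcodes) < n) {
      abort("barcode generation exhausted: could not draw enough unique barcodes")
    }
    barcodes <- barcodes[seq_len(n)]
    promoters <- sample(names(config$promoters), n, replace = TRUE,
                        prob = config$promoters / sum(config$promoters))
    codes <- promoter_index_codes(names(config$promoters))
    chroms <- paste0("chr", c(1:19, "X"))
    loci <- tibble(chrom = sample(chroms, n, replace = TRUE),
                   pos = sample.int(150000000L, n, replace = FALSE))
    tibble(
      barcode = barcodes,
      promoter = promoters,
      promoter_index = unname(codes[promoters]),
      chrom = loci$chrom,
      pos = loci$pos,
      strand = sample(c("+", "-"), n, replace = TRUE),
      mut_propensity = rbeta(n, config$propensity_shape[["a"]],
                             config$propensity_shape[["b"]]),
      target_region = cassette
    )
  })
}

# Apply one repair outcome to the wild-type region (ntDNA view coordinates).
# Returns list(seq, detail) where detail records the generating event.
mutate_region <- function(view, outcome, guide, config, ssodn,
                          f_stag) {
  seqc <- view$seq
  P <- view$pam_start
  cut_after <- after_from_junction(3L, P) # blunt cut 3|4
  detail <- list(ins_junction = NA_integer_, ins_seq = NA_character_,
                 staggered = NA, del_start = NA_integer_,
                 del_len = NA_integer_, del_seq = NA_character_)
  do_insertion <- function(s) {
    if (runif(1) < f_stag) {
      base4 <- ntdna_base_at(s, P, 4L)
      aft <- after_from_junction(4L, P) # template-dependent, junction 4|5
      detail$ins_junction <<- 4L
      detail$ins_seq <<- base4
      detail$staggered <<- TRUE
      str_insert(s, aft, base4)
    } else if (runif(1) < config$ins1_prob) {
      b <- sample(DNA_BASES, 1)
      detail$ins_junction <<- 3L
      detail$ins_seq <<- b
      detail$staggered <<- FALSE
      str_insert(s, cut_after, b)
    } else {
      w <- paste(sample(DNA_BASES, sample(2:6, 1), replace = TRUE),
                 collapse = "")
      detail$ins_junction <<- 3L
      detail$ins_seq <<- w
      detail$staggered <<- FALSE
      str_insert(s, cut_after, w)
    }
  }
  do_deletion <- function(s) {
    spike <- config$mh_spike
    if (!is.null(spike) && runif(1) < spike$prob &&
        identical(substr(s, P - 6L, P - 4L), spike$triplet) &&
        identical(substr(s, P - 3L, P - 1L), spike$triplet)) {
      start <- P - 6L # positions 6..4 upstream; ambiguous with 3..1
      len <- 3L
    } else {
      len <- 0L
      while (len < 1L || len > config$deletion_max) {
        len <- stats::rgeom(1, config$deletion_geom_p) + 1L
      }
      start <- sample(seq(P - 4L - len + 1L, P - 3L), 1)
      start <- max(1L, min(start, nchar(s) - len + 1L))
    }
    detail$del_start <<- start
    detail$del_len <<- len
    detail$del_seq <<- substr(s, start, start + len - 1L)
    str_delete(s, start, len)
  }
  out <- switch(outcome,
    wild_type = seqc,
    insertion = do_insertion(seqc),
    deletion = do_deletion(seqc),
    knockin = {
      detail$ins_junction <- 3L
      detail$ins_seq <- ssodn$insert
      detail$staggered <- FALSE
      str_insert(seqc, cut_after, ssodn$insert)
    },
    complex = {
      s <- do_deletion(seqc)
      b <- sample(DNA_BASES, 1)
      # second, separate event downstream of the PAM, so the two indels
      # never merge (deletions live upstream of junction 2|3)
      aft <- P + 4L
      detail$ins_junction <- -5L
      detail$ins_seq <- b
      s <- str_insert(s, aft, b)
      s
    },
    abort(sprintf("unknown outcome '%s'", outcome))
  )
  list(seq = out, detail = detail)
}

inject_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    chars <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(chars), n_err[i])
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1))
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate Cas9 amplicon reads for a library
#'
#' For each IR, coverage is drawn from the configured negative binomial and
#' each molecule is wild-type with probability `1 - p_ir * g_guide`, or else
#' an outcome from the repair mixture: deletions abutting or spanning the
#' 3|4 cut, template-dependent 1-bp insertions duplicating ntDNA nucleotide 4
#' at junction 4|5 (with the guide's staggered fraction), template-independent
#' insertions of a random base at the blunt 3|4 junction, complex
#' (deletion + insertion) events, and ssODN knock-ins when requested. Each
#' molecule is tagged with a random UID and emitted as
#' `[UID][barcode][promoter index][mutated region]` with i.i.d. substitution
#' sequencing errors. Per-IR child seeds are derived from the root seed, so
#' adding an IR never perturbs the reads of the others.
#'
#' @param library a [generate_reporter_library()] tibble.
#' @param guide a [guide_target()]; must occur in every construct's region.
#' @param config a [simulation_config()].
#' @param with_ssodn simulate an editing assay including the ssODN template.
#' @param ssodn ssODN definition (default [trip_ssodn()]).
#' @return list with `reads` (tibble `read_id`, `seq`) and `truth` (tibble
#'   of per-molecule generating outcomes).
#' @export
simulate_cas9_reads <- function(library, guide, config, with_ssodn = FALSE,
                                ssodn = trip_ssodn()) {
  region <- unique(library$target_region)
  if (length(region) != 1L) abort("library must share one target region")
  view <- tryCatch(ntdna_view(region, guide),
                   error = function(e) {
                     abort(sprintf(
                       "guide %s not found in target region of barcode %s",
                       guide$name, library$barcode[1]))
                   })
  g_eff <- config$guide_efficiency[[guide$name]] %||% 1
  f_stag <- if (!is.null(config$f_staggered)) {
    config$f_staggered[[guide$name]] %||% guide$f_staggered
  } else {
    guide$f_staggered
  }
  mix <- c(deletion = config$p_deletion, insertion = config$p_insertion,
           complex = config$complex_prob)
  mix <- mix / sum(mix)
  salt <- sum(utf8ToInt(guide$name)) + 17L * as.integer(with_ssodn)

  per_ir <- purrr::map(seq_len(nrow(library)), function(i) {
    ir <- library[i, ]
    with_seed(derive_seed(config$seed, i, salt), {
      cov <- rnbinom(1, mu = config$coverage_mean, size = config$coverage_size)
      if (cov == 0L) return(NULL)
      p_mut <- min(ir$mut_propensity * g_eff, 0.99)
      mutated <- runif(cov) < p_mut
      outcome <- rep("wild_type", cov)
      if (any(mutated)) {
        idx <- which(mutated)
        ki <- with_ssodn & runif(length(idx)) < config$knockin_prob
        outcome[idx[ki]] <- "knockin"
        n_other <- sum(!ki)
        if (n_other > 0) {
          outcome[idx[!ki]] <- sample(names(mix), n_other, replace = TRUE,
                                      prob = mix)
        }
      }
      uid <- random_dna(cov, config$uid_len)
      res <- purrr::map(outcome, function(o) {
        mutate_region(view, o, guide, config, ssodn, f_stag)
      })
      region_seq <- vapply(res, function(r) {
        if (view$strand == "sense") r$seq else revcomp(r$seq)
      }, character(1))
      seqs <- paste0(uid, ir$barcode, ir$promoter_index, region_seq)
      seqs <- inject_substitutions(seqs, config$seq_error_rate)
      truth <- bind_rows(purrr::map(res, ~as_tibble(.x$detail))) %>%
        mutate(
          barcode = ir$barcode, uid = uid,
          outcome = ifelse(outcome == "knockin", "insertion", outcome),
          knockin = outcome == "knockin",
          .before = 1
        )
      list(reads = tibble(
             read_id = sprintf("%s_%s_%05d", guide$name, ir$barcode,
                               seq_len(cov)),
             seq = seqs),
           truth = truth)
    })
  })
  per_ir <- purrr::compact(per_ir)
  list(
    reads = bind_rows(purrr::map(per_ir, "reads")),
    truth = bind_rows(purrr::map(per_ir, "truth"))
  )
}

#' Simulate per-IR mutation frequencies for a factorial pool design
#'
#' Builds a balanced locus x guide x ssODN table of per-IR mutation
#' frequencies with exactly programmed variance shares: each variance
#' component (locus, guide, locus x guide interaction, ssODN, residual) is
#' drawn, centred, and rescaled so its realised variance matches the
#' requested share of the total. Used to validate the eta-squared
#' decomposition.
#'
#' @param n_irs number of loci.
#' @param guides character vector of guide labels (>= 2 for a guide effect).
#' @param ssodn_levels logical levels of ssODN inclusion.
#' @param var_shares named shares for `locus`, `guide`, `interaction`,
#'   `ssodn`; the remainder is residual noise. Must sum to <= 1.
#' @param mean_freq,total_sd location and scale of the frequencies.
#' @param promoters named promoter weights; each locus gets one promoter
#'   (nested), with no programmed promoter effect.
#' @param seed RNG seed.
#' @return tibble with `barcode`, `promoter`, `guide`, `ssodn`, `mut_freq`.
#' @export
simulate_frequency_table <- function(n_irs = 300L,
                                     guides = c("sgRNA2", "sgRNA3"),
                                     ssodn_levels = c(FALSE, TRUE),
                                     var_shares = c(locus = 0.80,
                                                    guide = 0.12,
                                                    interaction = 0.049,
                                                    ssodn = 0.002),
                                     mean_freq = 0.45, total_sd = 0.15,
                                     promoters = trip_pool_promoters(),
                                     seed = 1L) {
  if (sum(var_shares) > 1) abort("`var_shares` must sum to <= 1")
  resid_share <- 1 - sum(var_shares)
  V <- total_sd^2
  # centre and rescale so the *population* variance of the component equals
  # its programmed absolute share (critical for 2-level factors, where the
  # sample sd would halve the realised share)
  scale_to <- function(x, v) {
    x <- x - mean(x)
    s <- sqrt(mean(x^2))
    if (s == 0) return(x)
    x / s * sqrt(v)
  }
  with_seed(seed, {
    barcodes <- random_dna(n_irs, 18L)
    promoter <- sample(names(promoters), n_irs, replace = TRUE,
                       prob = promoters / sum(promoters))
    a <- scale_to(rnorm(n_irs), var_shares[["locus"]] * V)
    b <- scale_to(rnorm(length(guides)), var_shares[["guide"]] * V)
    cc <- scale_to(rnorm(length(ssodn_levels)), var_shares[["ssodn"]] * V)
    ab <- matrix(rnorm(n_irs * length(guides)), n_irs)
    ab <- ab - rowMeans(ab)
    ab <- sweep(ab, 2, colMeans(ab))
    ab <- scale_to(as.vector(ab), var_shares[["interaction"]] * V)
    ab <- matrix(ab, n_irs)
    grid <- tidyr::expand_grid(ir = seq_len(n_irs),
                               gi = seq_along(guides),
                               si = seq_along(ssodn_levels))
    eps <- scale_to(rnorm(nrow(grid)), resid_share * V)
    grid %>%
      mutate(
        barcode = barcodes[.data$ir],
        promoter = promoter[.data$ir],
        guide = guides[.data$gi],
        ssodn = ssodn_levels[.data$si],
        mut_freq = pmin(pmax(
          mean_freq + a[.data$ir] + b[.data$gi] + cc[.data$si] +
            ab[cbind(.data$ir, .data$gi)] + eps, 0), 1)
      ) %>%
      select("barcode", "promoter", "guide", "ssodn", "mut_freq")
  })
}

#' Simulate genomic feature tracks with programmed correlations
#'
#' For each requested feature, builds a per-IR score achieving the requested
#' Pearson correlation with a supplied per-IR signal (scaled signal plus
#' Gaussian noise, orthogonalised so the realised correlation is tight), and
#' lays the scores out as constant-score intervals spanning each locus.
#'
#' @param library a [generate_reporter_library()] tibble.
#' @param effect_spec tibble with columns `feature`, `category`, `r`
#'   (target correlation, `|r| < 1`).
#' @param signal numeric per-IR signal, aligned with `library` rows.
#' @param seed RNG seed.
#' @param span half-width in bp of each interval around the locus.
#' @return tibble with `feature`, `category`, `chrom`, `start`, `end`,
#'   `score` (0-based half-open intervals).
#' @export
simulate_feature_tracks <- function(library, effect_spec, signal,
                                    seed = 1L, span = 1500L) {
  if (any(abs(effect_spec$r) >= 1)) {
    abort("requested |r| must be < 1")
  }
  n <- nrow(library)
  stopifnot(length(signal) == n)
  z <- as.vector(scale(signal))
  with_seed(derive_seed(seed, 0L, 3L), {
    purrr::pmap(effect_spec, function(feature, category, r, ...) {
      e <- rnorm(n)
      e <- resid(lm(e ~ z))
      e <- as.vector(scale(e))
      score <- r * z + sqrt(1 - r^2) * e
      tibble(feature = feature, category = category,
             chrom = library$chrom,
             start = pmax(0L, library$pos - span),
             end = library$pos + span,
             score = score)
    }) %>% bind_rows()
  })
}
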