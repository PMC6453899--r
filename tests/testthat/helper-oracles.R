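# Independent oracles, deliberately written with different algorithmic
# structure than the package implementations they check.

# Naive semi-global affine-gap DP: O(nm(n+m)) with explicit maximisation
# over all gap lengths (no three-matrix recurrence). Free end gaps in the
# query row (unaligned reference flanks); the query is fully consumed.
oracle_semiglobal_score <- function(query, ref, match = 2, mismatch = -2,
                                    gap_open = -5, gap_extend = -0.5,
                                    initial = 30) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q)
  m <- length(r)
  gapcost <- function(L) -(abs(gap_open) + (L - 1) * abs(gap_extend))
  H <- matrix(-Inf, n + 1, m + 1)
  H[1, ] <- 0 # free leading reference flank
  for (i in 1:n) {
    # leading query overhang (gap in reference) is penalised
    H[i + 1, 1] <- gapcost(i)
    for (j in 1:m) {
      s <- if (q[i] == r[j] && q[i] != "N") match else mismatch
      best <- H[i, j] + s
      for (L in 1:j) { # gap in query of length L ending at column j
        cand <- H[i + 1, j + 1 - L] + gapcost(L)
        if (cand > best) best <- cand
      }
      for (L in 1:i) { # gap in reference of length L ending at row i
        cand <- H[i + 1 - L, j + 1] + gapcost(L)
        if (cand > best) best <- cand
      }
      H[i + 1, j + 1] <- best
    }
  }
  max(H[n + 1, ]) + initial # free trailing reference flank
}

# Brute-force ambiguity windows: group junctions by literal identity of the
# full mutated sequence after inserting `base` at each junction.
oracle_ambiguity_windows <- function(ntdna, pam_start, junctions = 0:8) {
  res <- list()
  for (b in c("A", "C", "G", "T")) {
    muts <- vapply(junctions, function(j) {
      after <- pam_start - j - 1L
      paste0(substr(ntdna, 1, after), b,
             substr(ntdna, after + 1L, nchar(ntdna)))
    }, character(1))
    grp <- match(muts, unique(muts))
    for (g in unique(grp)) {
      js <- junctions[grp == g]
      res[[length(res) + 1L]] <- data.frame(
        base = b, junction = js,
        window_id = sprintf("%s:%d-%d", b, min(js), max(js)),
        ambiguous = length(js) > 1L)
    }
  }
  out <- do.call(rbind, res)
  out[order(out$base, out$junction), ]
}

# Independent hairpin expected-read builder (different arithmetic: works on
# character vectors and explicit complement lookup).
oracle_hairpin_read <- function(duplex, pam_start, nt_term, t_term, loop) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(duplex, "")[[1]]
  top <- ch[(pam_start - nt_term):length(ch)]
  bottom_tmpl <- ch[(pam_start - t_term):length(ch)]
  bottom <- rev(unname(comp[bottom_tmpl]))
  paste(c(bottom, strsplit(loop, "")[[1]], top), collapse = "")
}

# Exact two-sample Wilcoxon rank-sum p-value by full enumeration of group
# assignments (two-sided), for small samples without ties.
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  w_all <- apply(combs, 2, function(idx) {
    sum(ranks[idx]) - n * (n + 1) / 2
  })
  mu <- n * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# Hand-applied Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# small error-free simulation shared by several tests
tiny_assay <- function(seed = 42, n_irs = 4, coverage_mean = 50,
                       guide = trip_guides()$sgRNA3, ...) {
  cfg <- simulation_config(seed = seed, n_irs = n_irs,
                           coverage_mean = coverage_mean,
                           seq_error_rate = 0, ...)
  lib <- generate_reporter_library(cfg)
  sim <- simulate_cas9_reads(lib, guide, cfg)
  parsed <- parse_amplicons(sim$reads, lib)
  calls <- collapse_uids(call_reads(parsed, lib, guide))
  list(cfg = cfg, lib = lib, sim = sim, parsed = parsed, calls = calls,
       guide = guide)
}
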