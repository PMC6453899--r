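test_that("reporter libraries honour size, promoters and determinism", {
  cfg <- simulation_config(seed = 2, n_irs = 36, promoters = c(PGK = 1))
  lib <- generate_reporter_library(cfg)
  expect_equal(nrow(lib), 36)
  expect_true(all(lib$promoter == "PGK"))
  expect_false(anyDuplicated(lib$barcode) > 0)
  expect_false(anyDuplicated(paste(lib$chrom, lib$pos)) > 0)
  # byte-identical under the same seed
  expect_identical(lib, generate_reporter_library(cfg))
  # different seed differs
  expect_false(identical(
    lib, generate_reporter_library(simulation_config(seed = 3, n_irs = 36))))
  # empty library rejected
  expect_error(generate_reporter_library(simulation_config(n_irs = 0)),
               ">= 1")
  # protospacer+PAM sites occur exactly once per guide in the cassette
  cass <- trip_cassette()
  for (g in trip_guides()) {
    site <- paste0(g$protospacer, g$pam)
    expect_equal(length(gregexpr(site, cass, fixed = TRUE)[[1]]) *
                   (gregexpr(site, cass, fixed = TRUE)[[1]][1] != -1), 1)
    expect_false(grepl(site, revcomp(cass), fixed = TRUE))
  }
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(p_deletion = 1.2), "probabilities")
  expect_error(simulation_config(coverage_mean = 0), "coverage_mean")
  expect_error(simulation_config(f_staggered = c(sgRNA1 = -0.1)),
               "f_staggered")
  expect_error(simulation_config(promoters = c(2, 1)), "named")
})

test_that("degenerate insertion mixtures behave as configured", {
  g <- trip_guides()$sgRNA3 # ntDNA base 4 = T
  # f_staggered = 1: every insertion duplicates base 4 at junction 4|5
  cfg1 <- simulation_config(seed = 21, n_irs = 3, coverage_mean = 80,
                            p_deletion = 0, p_insertion = 1,
                            complex_prob = 0, ins1_prob = 1,
                            seq_error_rate = 0,
                            f_staggered = c(sgRNA3 = 1))
  lib <- generate_reporter_library(cfg1)
  sim1 <- simulate_cas9_reads(lib, g, cfg1)
  ins1 <- sim1$truth[sim1$truth$outcome == "insertion", ]
  expect_gt(nrow(ins1), 50)
  expect_true(all(ins1$ins_seq == "T"))
  expect_true(all(ins1$ins_junction == 4L))
  # f_staggered = 0, large n: inserted bases uniform within 3 sigma
  cfg0 <- simulation_config(seed = 22, n_irs = 8, coverage_mean = 550,
                            propensity_shape = c(a = 50, b = 1),
                            p_deletion = 0, p_insertion = 1,
                            complex_prob = 0, ins1_prob = 1,
                            seq_error_rate = 0,
                            f_staggered = c(sgRNA3 = 0))
  lib0 <- generate_reporter_library(cfg0)
  sim0 <- simulate_cas9_reads(lib0, g, cfg0)
  ins0 <- sim0$truth[sim0$truth$outcome == "insertion", ]
  n <- nrow(ins0)
  expect_gte(n, 4000)
  for (b in c("A", "C", "G", "T")) {
    k <- sum(ins0$ins_seq == b)
    sigma <- sqrt(n * 0.25 * 0.75)
    expect_lt(abs(k - n * 0.25), 3 * sigma)
  }
})

test_that("microhomology spike recovers the programmed CGG-loss fraction", {
  g <- trip_guides()$sgRNA1 # CGGCGG at positions 1-6
  cfg <- simulation_config(seed = 31, n_irs = 10, coverage_mean = 400,
                           propensity_shape = c(a = 50, b = 1),
                           p_deletion = 1, p_insertion = 0,
                           complex_prob = 0, seq_error_rate = 0,
                           mh_spike = list(triplet = "CGG", prob = 0.4))
  lib <- generate_reporter_library(cfg)
  sim <- simulate_cas9_reads(lib, g, cfg)
  dels <- sim$truth[sim$truth$outcome == "deletion", ]
  n <- nrow(dels)
  expect_gt(n, 2000)
  frac_cgg3 <- mean(dels$del_len == 3 & dels$del_seq == "CGG")
  sigma <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(frac_cgg3 - 0.4), 3 * sigma + 0.02)
})

test_that("truth table is consistent with the emitted reads", {
  asy <- tiny_assay(seed = 12, n_irs = 5, coverage_mean = 80)
  # one read per truth row, and (error-free) a read's target region equals
  # the wild-type cassette exactly iff its truth outcome is wild-type
  expect_equal(nrow(asy$sim$reads), nrow(asy$sim$truth))
  joined <- dplyr::inner_join(asy$parsed, asy$sim$truth,
                              by = c("barcode", "uid"))
  expect_equal(nrow(joined), nrow(asy$sim$truth))
  expect_identical(joined$target_seq == trip_cassette(),
                   joined$outcome == "wild_type")
  # truth frequencies therefore equal read-derived frequencies exactly
  expect_equal(mean(joined$target_seq != trip_cassette()),
               mean(asy$sim$truth$outcome != "wild_type"))
})

test_that("identical config and seed give byte-identical reads", {
  cfg <- simulation_config(seed = 77, n_irs = 3, coverage_mean = 40)
  lib <- generate_reporter_library(cfg)
  g <- trip_guides()$sgRNA2
  a <- simulate_cas9_reads(lib, g, cfg)
  b <- simulate_cas9_reads(lib, g, cfg)
  expect_identical(a, b)
  # per-IR child streams: dropping the last IR leaves the others untouched
  c3 <- simulate_cas9_reads(lib[1:2, ], g, cfg)
  expect_identical(c3$reads$seq,
                   a$reads$seq[grepl(paste(lib$barcode[1:2], collapse = "|"),
                                     a$reads$read_id)])
})

test_that("feature tracks achieve requested correlations", {
  cfg <- simulation_config(seed = 8, n_irs = 500)
  lib <- generate_reporter_library(cfg)
  signal <- lib$mut_propensity
  spec <- tibble::tibble(feature = c("null_track", "coupled_track"),
                         category = "chip", r = c(0, 0.6))
  tracks <- simulate_feature_tracks(lib, spec, signal, seed = 4)
  scores <- tracks %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::summarise(r_hat = stats::cor(.data$score, signal))
  r0 <- scores$r_hat[scores$feature == "null_track"]
  r6 <- scores$r_hat[scores$feature == "coupled_track"]
  expect_lt(abs(r0), 0.15)
  expect_gt(r6, 0.5)
  expect_lt(r6, 0.7)
  expect_error(
    simulate_feature_tracks(lib, tibble::tibble(feature = "x",
                                                category = "c", r = 1.1),
                            signal),
    "< 1")
})
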