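make_calls <- function(outcomes, barcode = "BC1", assay = "a1",
                       knockin = FALSE) {
  n <- length(outcomes)
  tibble::tibble(
    read_id = sprintf("%s_%s_r%d", assay, barcode, seq_len(n)),
    barcode = barcode, uid = sprintf("u%06d", seq_len(n)),
    outcome = outcomes,
    knockin = rep_len(knockin, n), score = 70, status = "ok",
    descriptor = "x", deletions = list(NULL), insertions = list(NULL),
    assay = assay)
}

test_that("profiles compute outcome fractions and apply the coverage filter", {
  calls <- make_calls(c(rep("wild_type", 50), rep("deletion", 30),
                        rep("insertion", 15), rep("complex", 5)))
  pr <- compute_profiles(calls, min_coverage = 30)
  expect_equal(pr$coverage, 100)
  expect_equal(c(pr$wild_type, pr$deletion, pr$insertion, pr$complex),
               c(0.50, 0.30, 0.15, 0.05))
  expect_equal(pr$mut_freq, 0.5)
  expect_equal(pr$wild_type + pr$deletion + pr$insertion + pr$complex, 1,
               tolerance = 1e-9)
  # an IR with 29 molecules in one assay is excluded from every assay
  multi <- dplyr::bind_rows(
    make_calls(rep("wild_type", 40), "BC1", "a1"),
    make_calls(rep("wild_type", 29), "BC1", "a2"),
    make_calls(rep("deletion", 35), "BC2", "a1"),
    make_calls(rep("deletion", 31), "BC2", "a2"))
  pr2 <- compute_profiles(multi, min_coverage = 30)
  expect_setequal(unique(pr2$barcode), "BC2")
  # all wild-type -> zero mutation frequency
  pr3 <- compute_profiles(make_calls(rep("wild_type", 30)))
  expect_equal(pr3$mut_freq, 0)
  # empty input warns and returns empty
  expect_warning(pr4 <- compute_profiles(make_calls(character(0))), "empty")
  expect_equal(nrow(pr4), 0)
  # knock-in split: knockin_freq + error_insertion_freq = insertion fraction
  ki <- make_calls(c(rep("insertion", 10), rep("wild_type", 30)),
                   knockin = c(rep(TRUE, 4), rep(FALSE, 36)))
  pr5 <- compute_profiles(ki, min_coverage = 30)
  expect_equal(pr5$knockin_freq + pr5$error_insertion_freq, pr5$insertion)
  expect_equal(pr5$knockin_freq, 0.1)
})

test_that("replicate pooling is order-invariant", {
  a <- make_calls(c(rep("deletion", 20), rep("wild_type", 20)), "BC1", "rep")
  b <- make_calls(c(rep("deletion", 5), rep("wild_type", 25)), "BC1", "rep")
  b$uid <- paste0("b", b$uid)
  p_ab <- compute_profiles(dplyr::bind_rows(a, b), min_coverage = 30)
  p_ba <- compute_profiles(dplyr::bind_rows(b, a), min_coverage = 30)
  expect_equal(p_ab, p_ba)
  expect_equal(p_ab$deletion, 25 / 70)
})

test_that("size spectra report per-size frequencies and summary fractions", {
  asy <- tiny_assay(seed = 14, n_irs = 5, coverage_mean = 150)
  sp <- size_spectra(asy$calls)
  expect_equal(sum(sp$deletions$freq), 1, tolerance = 1e-9)
  expect_equal(sum(sp$insertions$freq), 1, tolerance = 1e-9)
  # compare against the generator's truth directly
  truth_del <- asy$sim$truth$del_len[asy$sim$truth$outcome == "deletion"]
  expect_equal(sp$frac_del_lt10, mean(truth_del < 10), tolerance = 0.02)
  # geometric sizes match the generator law within 3 sigma at size 1
  p <- asy$cfg$deletion_geom_p
  p1_theory <- p / (1 - (1 - p)^asy$cfg$deletion_max)
  n <- length(truth_del)
  sigma <- sqrt(p1_theory * (1 - p1_theory) / n)
  obs1 <- sp$deletions$freq[sp$deletions$size == 1]
  expect_lt(abs(obs1 - p1_theory), 3 * sigma + 0.01)
})

test_that("deletion boundary weights split over ambiguous placements", {
  cass <- trip_cassette()
  g <- trip_guides()$sgRNA1
  v <- crisprtrip:::ntdna_view(cass, g)
  p <- alignment_params()
  call_one <- function(seq) {
    al <- align_semi_global(seq, v$seq, p)
    attr(al, "full_reference") <- v$seq
    cl <- call_mutation(al, v$pam_start)
    out <- tibble::tibble(read_id = "r", barcode = "BC", uid = "u",
                          outcome = cl$outcome, knockin = cl$knockin,
                          score = cl$score, status = "ok", descriptor = "d",
                          deletions = list(cl$deletions),
                          insertions = list(cl$insertions))
    attr(out, "pam_start") <- v$pam_start
    attr(out, "ntdna_region") <- v$seq
    out
  }
  # unambiguous deletion abutting 3|4: remove positions 4..5 in a context
  # where no equivalent placement exists
  del_45 <- crisprtrip:::str_delete(v$seq, v$pam_start - 5L, 2L)
  bf <- deletion_boundary_frequencies(call_one(del_45))
  w34 <- bf$weight[bf$junction == 3]
  expect_equal(w34, 1)
  # CGG loss in the CGGCGG context: deleting any 3 consecutive bases of the
  # repeat gives the same product, so the equivalence window has 4
  # placements (positions 6-4, 5-3, 4-2, 3-1); the placements at 6-4 and
  # 3-1 abut junction 3|4 (m/k = 2/4) and only 4-2 abuts 4|5 (1/4)
  del_cgg <- crisprtrip:::str_delete(v$seq, v$pam_start - 6L, 3L)
  cl <- call_one(del_cgg)
  win <- cl$deletions[[1]]$window[[1]]
  expect_length(win, 4)
  expect_setequal(v$pam_start - win, 3:6) # left boundary junctions
  bf2 <- deletion_boundary_frequencies(cl)
  expect_equal(bf2$weight[bf2$junction == 3], 0.5)
  expect_equal(bf2$weight[bf2$junction == 4], 0.25)
  expect_error(deletion_boundary_frequencies(cl, junctions = 25L),
               "protospacer")
})

test_that("insertion base distributions follow the staggered mixture", {
  g <- trip_guides()$sgRNA3
  cfg <- simulation_config(seed = 33, n_irs = 8, coverage_mean = 400,
                           propensity_shape = c(a = 50, b = 1),
                           p_deletion = 0, p_insertion = 1,
                           complex_prob = 0, ins1_prob = 1,
                           seq_error_rate = 0,
                           f_staggered = c(sgRNA3 = 0.5))
  lib <- generate_reporter_library(cfg)
  sim <- simulate_cas9_reads(lib, g, cfg)
  parsed <- parse_amplicons(sim$reads, lib)
  calls <- collapse_uids(call_reads(parsed, lib, g))
  dist <- insertion_base_distribution(calls)
  tfrac <- dist$overall$freq[dist$overall$base == "T"]
  n <- sum(dist$overall$n)
  expect_gt(n, 2000)
  # closed-form mixture expectation: f + (1 - f) / 4
  expect_lt(abs(tfrac - 0.625), 3 * sqrt(0.625 * 0.375 / n))
  # degenerate case: all insertions of one base
  one <- calls[purrr::map_lgl(calls$insertions,
                              ~!is.null(.x) && all(.x$seq == "T")), ]
  attr(one, "pam_start") <- attr(calls, "pam_start")
  attr(one, "ntdna_region") <- attr(calls, "ntdna_region")
  d1 <- insertion_base_distribution(one)
  expect_equal(d1$overall$freq, c(0, 0, 0, 1))
})

test_that("expression normalisation uses log2 ratios with pseudocounts", {
  cdna <- tibble::tibble(barcode = c("b1", "b2", "b3", "b4"),
                         count = c(100L, 0L, 50L, 10L))
  gdna <- tibble::tibble(barcode = c("b1", "b2", "b3"),
                         count = c(100L, 20L, 0L))
  expect_warning(expr <- compute_ir_expression(cdna, gdna), "excluded")
  expect_setequal(expr$barcode, c("b1", "b2"))
  expect_equal(expr$expression[expr$barcode == "b1"], 0)
  expect_true(is.finite(expr$expression[expr$barcode == "b2"]))
  # doubling both counts leaves the ratio approximately invariant
  e1 <- suppressWarnings(compute_ir_expression(cdna, gdna))
  e2 <- suppressWarnings(compute_ir_expression(
    dplyr::mutate(cdna, count = count * 2L),
    dplyr::mutate(gdna, count = count * 2L)))
  expect_equal(e1$expression[e1$barcode == "b1"],
               e2$expression[e2$barcode == "b1"], tolerance = 0.05)
})
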