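hc_context <- function() {
  v <- crisprtrip:::ntdna_view(trip_cassette(), trip_guides()$sgRNA3)
  list(duplex = v$seq, pam_start = v$pam_start)
}

test_that("hairpin reads encode end conformations around the apex", {
  ctx <- hc_context()
  loop <- "GCGAAGC"
  r0 <- crisprtrip:::hairpin_read(ctx$duplex, ctx$pam_start, 3L, 3L, loop)
  # blunt reference equals the independently built oracle read
  expect_identical(r0, oracle_hairpin_read(ctx$duplex, ctx$pam_start,
                                           3L, 3L, loop))
  # 5' 1-nt overhang (3|4t, 4|5nt): one-base apex duplication of ntDNA
  # base 4 (T in this context)
  r1 <- crisprtrip:::hairpin_read(ctx$duplex, ctx$pam_start, 4L, 3L, loop)
  expect_equal(nchar(r1) - nchar(r0), 1)
  al <- align_semi_global(gsub("C", "T", r1), gsub("C", "T", r0))
  ops <- alignment_ops(al)
  expect_equal(ops$op, "ins")
  expect_equal(ops$seq, "T")
  # 3' 1-nt overhang with recessed top strand (2|3t... termini (2,3)):
  # one-base apex loss
  r2 <- crisprtrip:::hairpin_read(ctx$duplex, ctx$pam_start, 2L, 3L, loop)
  expect_equal(nchar(r2) - nchar(r0), -1)
  expect_error(crisprtrip:::hairpin_read(ctx$duplex, ctx$pam_start,
                                         200L, 3L, loop), "outside")
})

test_that("enumeration groups equal brute-force sequence identity", {
  ctx <- hc_context()
  enum <- enumerate_structures(ctx$duplex, ctx$pam_start)
  st <- enum$structures
  # oracle: rebuild every expected read independently and group by identity
  oracle_reads <- gsub("C", "T", purrr::map2_chr(
    st$nt_term, st$t_term,
    ~oracle_hairpin_read(ctx$duplex, ctx$pam_start, .x, .y, enum$loop)))
  expect_identical(st$expected_seq, oracle_reads)
  oracle_grp <- match(oracle_reads, unique(oracle_reads))
  # same partition: groups must be identical up to relabelling
  expect_equal(length(unique(st$group_id)), length(unique(oracle_grp)))
  expect_true(all(tapply(oracle_grp, st$group_id,
                         function(x) length(unique(x)) == 1L)))
  expect_true(all(tapply(st$group_id, oracle_grp,
                         function(x) length(unique(x)) == 1L)))
  # blunt structure is its own reference: empty indel signature
  blunt_sig <- st$signature[st$t_term == 3 & st$nt_term == 3]
  expect_equal(blunt_sig, "|")
  expect_error(enumerate_structures(ctx$duplex, ctx$pam_start,
                                    max_overhang = 20), "half the window")
})

test_that("pattern extraction applies the alignment quality filters", {
  ctx <- hc_context()
  enum <- enumerate_structures(ctx$duplex, ctx$pam_start)
  # reference-identical read: empty signature
  ok <- extract_end_pattern(enum$reference, enum)
  expect_equal(ok$status, "ok")
  expect_equal(ok$signature, "|")
  # 49-bp fragment fails the length filter
  short <- substr(enum$reference, enum$apex - 24, enum$apex + 24)
  expect_equal(extract_end_pattern(short, enum)$status, "short_alignment")
  # a read with > 5 gap columns is rejected
  gappy <- enum$reference
  for (off in c(-20, -14, 8, 14, 20, 24)) {
    gappy <- crisprtrip:::str_delete(gappy, enum$apex + off, 1L)
  }
  expect_equal(extract_end_pattern(gappy, enum)$status, "gappy")
  # a read covering less than 50 bp around the target site is rejected
  offcut <- substr(enum$reference, enum$apex - 10, nchar(enum$reference))
  expect_equal(extract_end_pattern(offcut, enum)$status, "no_span")
})

test_that("substitution masking is surgical and idempotent", {
  sigs <- c("I3:T|S-2:T>C,S5:T>C", "|S1:T>C,S2:G>A", "D-1:AC|")
  m <- mask_substitutions(sigs)
  expect_equal(m$signatures, c("I3:T|", "|", "D-1:AC|"))
  expect_equal(sum(m$stats$n), 4)
  expect_equal(m$stats$n[m$stats$type == "T>C"], 3)
  # idempotent
  expect_equal(mask_substitutions(m$signatures)$signatures, m$signatures)
})

test_that("mixtures are recovered through the noisy round trip", {
  ctx <- hc_context()
  enum <- enumerate_structures(ctx$duplex, ctx$pam_start)
  cfg <- simulation_config(seed = 61, bisulfite_failure_rate = 0.05)
  mix <- tibble::tibble(t_term = c(3L, 3L), nt_term = c(3L, 4L),
                        weight = c(0.6, 0.4))
  sim <- simulate_hcodes_reads(ctx$duplex, ctx$pam_start, mix,
                               n_reads = 800, config = cfg)
  # truth matches the drawn mixture within 3 sigma
  p_hat <- mean(sim$truth$nt_term == 4L)
  expect_lt(abs(p_hat - 0.4), 3 * sqrt(0.4 * 0.6 / 800))
  uniq <- unique(sim$reads$seq)
  pat <- dplyr::bind_rows(purrr::map(uniq, extract_end_pattern,
                                     enumeration = enum))
  pat$seq <- uniq
  obs <- dplyr::left_join(sim$reads, pat, by = "seq")
  tab <- match_and_rank(obs, enum, mask = TRUE)
  blunt_row <- grepl("(3|4t, 3|4nt)", tab$label, fixed = TRUE)
  stag_row <- grepl("(3|4t, 4|5nt)", tab$label, fixed = TRUE)
  f_blunt <- sum(tab$freq[blunt_row])
  f_stag <- sum(tab$freq[stag_row])
  expect_lt(abs(f_blunt - 0.6), 3 * sqrt(0.6 * 0.4 / 800) + 0.05)
  expect_lt(abs(f_stag - 0.4), 3 * sqrt(0.4 * 0.6 / 800) + 0.05)
  # frequencies sum to one over groups plus "other"
  expect_equal(sum(tab$freq), 1, tolerance = 1e-9)
  # weight sanity checks on the mixture argument
  expect_error(simulate_hcodes_reads(ctx$duplex, ctx$pam_start,
                                     dplyr::mutate(mix, weight = c(1, 1)),
                                     config = cfg), "sum to 1")
  expect_error(simulate_hcodes_reads(
    ctx$duplex, ctx$pam_start,
    tibble::tibble(t_term = 3L, nt_term = 40L, weight = 1),
    config = cfg), "outside")
})

test_that("bisulfite failures appear only at original-C positions", {
  ctx <- hc_context()
  cfg <- simulation_config(seed = 62, bisulfite_failure_rate = 0.2)
  mix <- tibble::tibble(t_term = 3L, nt_term = 3L, weight = 1)
  sim <- simulate_hcodes_reads(ctx$duplex, ctx$pam_start, mix,
                               n_reads = 50, config = cfg)
  clean <- crisprtrip:::hairpin_read(ctx$duplex, ctx$pam_start, 3L, 3L,
                                     "GCGAAGC")
  c_pos <- which(strsplit(clean, "")[[1]] == "C")
  for (s in sim$reads$seq) {
    chars <- strsplit(s, "")[[1]]
    ref <- strsplit(gsub("C", "T", clean), "")[[1]]
    diffs <- which(chars != ref)
    expect_true(all(diffs %in% c_pos))
    expect_true(all(chars[diffs] == "C"))
  }
  # rate 0: reads identical to the converted reference
  cfg0 <- simulation_config(seed = 63, bisulfite_failure_rate = 0)
  sim0 <- simulate_hcodes_reads(ctx$duplex, ctx$pam_start, mix,
                                n_reads = 10, config = cfg0)
  expect_true(all(sim0$reads$seq == gsub("C", "T", clean)))
})
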