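test_that("ambiguity windows follow runs of identical bases", {
  # context C.A.T upstream of the PAM: inserting A at C|A or A|T is the
  # same mutation -> one window of 2 junctions
  w <- find_ambiguity_windows("CATAGG", 4L, junctions = 0:2)
  wa <- w[w$base == "A", ]
  expect_equal(wa$window_id[wa$junction %in% 1:2], rep("A:1-2", 2))
  expect_true(all(wa$ambiguous[wa$junction %in% 1:2]))
  # a run of three As induces a window of 4 junctions
  w3 <- find_ambiguity_windows("GCAAATGG", 6L, junctions = 0:4)
  wa3 <- w3[w3$base == "A" & w3$ambiguous, ]
  expect_equal(nrow(wa3), 4)
  expect_equal(unique(wa3$window_id), "A:0-3")
  # a base absent from the neighbourhood is unambiguous at every junction
  wg <- w3[w3$base == "C", ]
  expect_true(all(!wg$ambiguous[wg$junction <= 2]))
})

test_that("window construction equals the brute-force oracle", {
  # a reduced sweep; the 1000-sequence contract runs in the acceptance suite
  set.seed(99)
  for (i in 1:100) {
    ntdna <- paste0(random_dna_str(20), "AGG")
    got <- find_ambiguity_windows(ntdna, 21L) %>%
      dplyr::arrange(.data$base, .data$junction)
    want <- oracle_ambiguity_windows(ntdna, 21L)
    expect_equal(got$window_id, want$window_id, info = ntdna)
    expect_equal(got$ambiguous, want$ambiguous, info = ntdna)
  }
})

test_that("count tables split unambiguous counts from window totals", {
  asy <- tiny_assay(seed = 44, n_irs = 5, coverage_mean = 200,
                    p_deletion = 0, p_insertion = 1, complex_prob = 0,
                    ins1_prob = 1)
  tab <- insertion_count_table(asy$calls)
  n_ins <- sum(purrr::map_int(asy$calls$insertions, function(x) {
    if (is.null(x)) 0L else sum(x$length == 1L)
  }))
  # total insertions = sum of unambiguous + window counts (all 1-bp
  # insertions here land inside the junction range)
  expect_equal(sum(tab$counts$unambiguous) + sum(tab$windows$count), n_ins)
  expect_true(all(tab$counts$unambiguous >= 0))
  # caller-convention independence: forcing every ambiguous insertion to
  # the 5'-most junction of its window leaves the table unchanged
  calls5 <- asy$calls
  calls5$insertions <- purrr::map(calls5$insertions, function(x) {
    if (is.null(x)) return(x)
    x$window <- purrr::map(x$window, ~sort(.x)) # placements, not order
    x$after <- purrr::map_int(x$window, min)
    x
  })
  attributes(calls5)[c("pam_start", "ntdna_region")] <-
    attributes(asy$calls)[c("pam_start", "ntdna_region")]
  tab5 <- insertion_count_table(calls5)
  expect_equal(tab5$counts, tab$counts)
  expect_equal(tab5$windows$count, tab$windows$count)
})

test_that("redistribution reproduces the worked examples", {
  ntdna <- paste0(trip_guides()$sgRNA3$protospacer, "CGG")
  ps <- 21L # position 4 = T, position 3 = C
  # blunt: window of 2 junctions, count 10, unambiguous totals 8 vs 2
  cnt <- tibble::tibble(junction = c(5L, 5L, 6L, 6L),
                        base = c("A", "C", "A", "C"),
                        unambiguous = c(5, 3, 1, 1))
  win <- tibble::tibble(window_id = "G:5-6", base = "G",
                        junctions = list(c(5L, 6L)), count = 10)
  tab <- as_insertion_count_table(cnt, win, ntdna, ps)
  rb <- redistribute_counts(tab, "blunt")
  expect_equal(rb$redistributed[rb$base == "G" & rb$junction == 5], 8)
  expect_equal(rb$redistributed[rb$base == "G" & rb$junction == 6], 2)
  # staggered: junction 4 likely for T, junction 3 unlikely with other-base
  # counts (3, 5, 1) -> mean 3 stays, remainder 7 moves to the likely site
  cnt2 <- tibble::tibble(junction = c(3L, 3L, 3L), base = c("A", "C", "G"),
                         unambiguous = c(3, 5, 1))
  win2 <- tibble::tibble(window_id = "T:3-4", base = "T",
                         junctions = list(c(3L, 4L)), count = 10)
  tab2 <- as_insertion_count_table(cnt2, win2, ntdna, ps)
  rs <- redistribute_counts(tab2, "staggered")
  expect_equal(rs$redistributed[rs$base == "T" & rs$junction == 3], 3)
  expect_equal(rs$redistributed[rs$base == "T" & rs$junction == 4], 7)
  # all-zero weights fall back to a uniform split
  win3 <- tibble::tibble(window_id = "G:7-8", base = "G",
                         junctions = list(c(7L, 8L)), count = 6)
  tab3 <- as_insertion_count_table(cnt2[0, ], win3, ntdna, ps)
  rz <- redistribute_counts(tab3, "blunt")
  expect_equal(rz$redistributed[rz$base == "G" & rz$junction %in% 7:8],
               c(3, 3))
  # no ambiguous windows: output equals the unambiguous table
  tab4 <- as_insertion_count_table(cnt2, win2[0, ], ntdna, ps)
  r4 <- redistribute_counts(tab4, "combined")
  expect_equal(r4$count, r4$unambiguous)
  expect_error(redistribute_counts(tab2, "sideways"))
})

test_that("redistribution conserves totals under all three models", {
  asy <- tiny_assay(seed = 55, n_irs = 6, coverage_mean = 250,
                    p_deletion = 0.2, p_insertion = 0.7, complex_prob = 0.1,
                    ins1_prob = 1)
  tab <- insertion_count_table(asy$calls)
  total_in <- sum(tab$counts$unambiguous) + sum(tab$windows$count)
  for (m in c("blunt", "staggered", "combined")) {
    r <- redistribute_counts(tab, m)
    expect_equal(sum(r$count), total_in, info = m)
    expect_equal(attr(r, "clamped"), 0L, info = m)
    expect_true(all(r$count >= 0), info = m)
  }
})

test_that("negative staggered remainders clamp to zero with a warning", {
  ntdna <- paste0(trip_guides()$sgRNA3$protospacer, "CGG")
  cnt <- tibble::tibble(junction = c(3L, 3L, 3L), base = c("A", "C", "G"),
                        unambiguous = c(40, 40, 40))
  win <- tibble::tibble(window_id = "T:3-4", base = "T",
                        junctions = list(c(3L, 4L)), count = 10)
  tab <- as_insertion_count_table(cnt, win, ntdna, 21L)
  expect_warning(r <- redistribute_counts(tab, "staggered"), "clamped")
  expect_equal(attr(r, "clamped"), 1L)
  expect_equal(r$redistributed[r$base == "T" & r$junction == 4], 0)
})

test_that("expected profiles carry the model signatures", {
  ntdna <- paste0(trip_guides()$sgRNA3$protospacer, "CGG") # base 4 = T
  b <- expected_profile("blunt", ntdna, 21L)
  expect_equal(unique(b$junction), 3L)
  expect_equal(b$weight, rep(0.25, 4))
  s <- expected_profile("staggered", ntdna, 21L)
  expect_equal(s$junction, 4L)
  expect_equal(s$base, "T")
  cmb <- expected_profile("combined", ntdna, 21L)
  expect_setequal(unique(cmb$junction), c(3L, 4L))
  expect_equal(sum(cmb$weight), 1)
})

test_that("concordance flags the blunt and staggered signatures", {
  ntdna <- paste0(trip_guides()$sgRNA3$protospacer, "CGG")
  flat <- tibble::tibble(junction = 3L, base = c("A", "C", "G", "T"),
                         unambiguous = 10, redistributed = 0, count = 10)
  mc <- model_concordance(flat, ntdna, 21L)
  expect_true(mc$concordant_blunt)
  spike <- tibble::tibble(junction = 4L, base = c("A", "C", "G", "T"),
                          unambiguous = c(0, 0, 0, 100),
                          redistributed = 0, count = c(0, 0, 0, 100))
  mc2 <- model_concordance(spike, ntdna, 21L)
  expect_equal(mc2$modal_base, "T")
  expect_equal(mc2$modal_share, 1)
  expect_true(mc2$concordant_staggered)
  # zero-count junctions are skipped
  zero <- dplyr::mutate(spike, count = 0)
  expect_equal(nrow(model_concordance(zero, ntdna, 21L)), 0)
})

test_that("count tables round-trip through TSV", {
  ntdna <- paste0(trip_guides()$sgRNA3$protospacer, "CGG")
  cnt <- tibble::tibble(junction = c(3L, 5L), base = c("A", "C"),
                        unambiguous = c(4, 2))
  win <- tibble::tibble(window_id = "T:3-4", base = "T",
                        junctions = list(c(3L, 4L)), count = 7)
  tab <- as_insertion_count_table(cnt, win, ntdna, 21L)
  td <- withr::local_tempdir()
  p <- file.path(td, "counts.tsv")
  write_insertion_counts(tab, p)
  back <- read_insertion_counts(p, ntdna, 21L)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$windows$count, tab$windows$count)
  expect_equal(back$windows$junctions, tab$windows$junctions)
})
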