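#' Find 1-bp insertion ambiguity windows on the non-target strand
#'
#' Inserting a base next to an identical neighbour produces a mutated
#' sequence indistinguishable from inserting it on the other side of that
#' neighbour; a run of k identical bases induces a window of k+1 equivalent
#' junctions. For each base this function groups the junctions of the
#' analysis range into maximal windows of consecutive ambiguous sites
#' (flanking runs of that base); junctions matching neither neighbour are
#' unambiguous (singleton windows).
#'
#' @param ntdna ntDNA sequence 5'->3' containing protospacer + PAM (PAM may
#'   be followed by further context).
#' @param pam_start 1-based index of the first PAM base in `ntdna`.
#' @param junctions integer junction range to analyse, `j` meaning `j|j+1`
#'   upstream of the PAM (default 0:8, i.e. 0|1 .. 8|9).
#' @return tibble with one row per (base, junction): `base`, `junction`,
#'   `window_id` (windows are `<base>:<min junction>-<max junction>`),
#'   `ambiguous` (window has more than one junction in range).
#' @export
find_ambiguity_windows <- function(ntdna, pam_start, junctions = 0:8) {
  assert_dna(ntdna, allow_n = FALSE, arg = "ntdna")
  chars <- strsplit(ntdna, "")[[1]]
  out <- purrr::map(DNA_BASES, function(b) {
    # window membership by run extension: junction j|j+1 joins the window of
    # the run of b it touches (positions are pam_start - k for position k)
    grp <- integer(length(junctions))
    for (i in seq_along(junctions)) {
      j <- junctions[i]
      # neighbours of the bond: position j+1 (5' side), position j (3' side)
      lo <- j # 3'-side position
      # extend across the run of b containing either neighbour
      if (base_at(chars, pam_start, j) == b) {
        # run continues toward the PAM: find its 3'-most position
        k <- j
        while (base_at(chars, pam_start, k - 1L) == b) k <- k - 1L
        grp[i] <- k # run end toward PAM identifies the window
      } else if (base_at(chars, pam_start, j + 1L) == b) {
        k <- j + 1L
        while (base_at(chars, pam_start, k - 1L) == b) k <- k - 1L
        grp[i] <- k
      } else {
        grp[i] <- -(j + 1000L) # unique singleton key
      }
    }
    tibble(base = b, junction = junctions, grp = grp) %>%
      group_by(.data$grp) %>%
      mutate(window_id = sprintf("%s:%d-%d", b, min(.data$junction),
                                 max(.data$junction)),
             ambiguous = n() > 1L) %>%
      ungroup() %>%
      select(-"grp")
  })
  bind_rows(out)
}

base_at <- function(chars, pam_start, k) {
  idx <- pam_start - k
  if (idx < 1L || idx > length(chars)) return("")
  chars[idx]
}

#' Build the per-junction 1-bp insertion count table
#'
#' Tallies UID-collapsed single-base insertion calls into the junction x base
#' grid of the analysis range: insertions whose placement window collapses
#' to one junction are unambiguous counts at that junction; insertions with
#' multiple equivalent placements accumulate on their ambiguity window,
#' awaiting model-based redistribution. Counts enter as window totals, so
#' the result does not depend on whether the upstream caller reports
#' ambiguous insertions at the 5'-most or 3'-most junction of a run.
#'
#' @param calls UID-collapsed calls from [collapse_uids()] (insertion
#'   outcomes with 1-bp inserts are used).
#' @param junctions junction analysis range (default 0:8).
#' @return an object of class `insertion_count_table`: list with `counts`
#'   (tibble `junction`, `base`, `unambiguous`), `windows` (tibble
#'   `window_id`, `base`, `junctions` list-column, `count`), `ntdna`,
#'   `pam_start`, `junction_range`.
#' @export
insertion_count_table <- function(calls, junctions = 0:8) {
  pam_start <- attr(calls, "pam_start")
  ntdna <- attr(calls, "ntdna_region")
  if (is.null(pam_start) || is.null(ntdna)) {
    abort("calls must carry 'pam_start' and 'ntdna_region' attributes")
  }
  ins <- unnest_indels(calls %>% filter(.data$outcome == "insertion"),
                       "insertions") %>%
    filter(.data$length == 1L)
  wins <- find_ambiguity_windows(ntdna, pam_start, junctions)

  # map each insertion to its junction set within range
  ins_j <- purrr::map(ins$window, function(afters) {
    j <- junction_from_after(afters, pam_start)
    sort(j[j %in% junctions])
  })
  keep <- lengths(ins_j) > 0L
  ins <- ins[keep, , drop = FALSE]
  ins_j <- ins_j[keep]
  key <- purrr::map2_chr(ins$seq, ins_j, function(b, js) {
    sprintf("%s:%d-%d", b, min(js), max(js))
  })

  tallies <- tibble(window_id = key) %>% count(.data$window_id)
  wins_grp <- wins %>%
    group_by(.data$window_id, .data$base, .data$ambiguous) %>%
    summarise(junctions = list(.data$junction), .groups = "drop") %>%
    left_join(tallies, by = "window_id") %>%
    mutate(count = tidyr::replace_na(.data$n, 0L)) %>%
    select(-"n")

  unmatched <- setdiff(key, wins_grp$window_id)
  if (length(unmatched)) {
    warn(sprintf("%d insertion(s) did not match a canonical window and were dropped",
                 sum(key %in% unmatched)))
  }

  counts <- wins_grp %>%
    filter(!.data$ambiguous) %>%
    mutate(junction = purrr::map_int(.data$junctions, 1L)) %>%
    select("junction", "base", unambiguous = "count")
  counts <- tidyr::expand_grid(junction = junctions, base = DNA_BASES) %>%
    left_join(counts, by = c("junction", "base")) %>%
    mutate(unambiguous = tidyr::replace_na(.data$unambiguous, 0L))

  structure(
    list(counts = counts,
         windows = wins_grp %>% filter(.data$ambiguous) %>%
           select("window_id", "base", "junctions", "count"),
         ntdna = ntdna, pam_start = pam_start, junction_range = junctions),
    class = "insertion_count_table")
}

#' @export
print.insertion_count_table <- function(x, ...) {
  cat(sprintf(
    "<insertion_count_table> junctions %d|%d..%d|%d: %d unambiguous, %d ambiguous in %d windows\n",
    min(x$junction_range), min(x$junction_range) + 1L,
    max(x$junction_range), max(x$junction_range) + 1L,
    sum(x$counts$unambiguous), sum(x$windows$count), nrow(x$windows)))
  invisible(x)
}

# downstream (PAM-side) ntDNA base of junction j|j+1 is position j
downstream_base <- function(ntdna, pam_start, j) {
  b <- ntdna_base_at(ntdna, pam_start, j)
  if (is.na(b)) "" else b
}

#' Redistribute ambiguous insertion counts under a cleavage model
#'
#' Spreads each ambiguity window's accumulated count over its junctions
#' according to a Cas9 cleavage/repair model:
#'
#' * `"blunt"` (template-independent insertions): proportional to the total
#'   unambiguous insertion counts (all four bases) at each junction of the
#'   window; a window with all-zero weights is split uniformly.
#' * `"staggered"` (template-dependent fill-in of a 1-nt 5' overhang):
#'   junctions whose downstream (PAM-side) ntDNA base equals the inserted
#'   base are "likely"; each unlikely junction receives the mean of the
#'   unambiguous counts of the other three bases at that junction, and the
#'   remainder of the window count goes to the likely junctions
#'   proportionally to unambiguous weights. A negative remainder is clamped
#'   to zero and reported.
#' * `"combined"`: the staggered rule governs junction 4|5 and the
#'   blunt/proportional rule every other junction. In a window containing a
#'   template-likely junction 4, the other junctions receive their
#'   template-independent estimate (the other-base mean) and 4|5 attracts
#'   the remainder; a template-unlikely junction 4 takes its other-base
#'   mean first and the rest of the count is spread proportionally over the
#'   other junctions; windows not touching 4|5 are split proportionally.
#'
#' Totals are conserved exactly except where clamping occurs (reported via
#' the `"clamped"` attribute and a warning).
#'
#' @param table an [insertion_count_table()].
#' @param model `"blunt"`, `"staggered"` or `"combined"`.
#' @return tibble with `junction`, `base`, `unambiguous`, `redistributed`
#'   (the share of ambiguous counts assigned here) and `count` (their sum);
#'   attribute `"clamped"` counts clamping events.
#' @export
redistribute_counts <- function(table, model = c("blunt", "staggered",
                                                 "combined")) {
  if (!inherits(table, "insertion_count_table")) {
    abort("`table` must be an insertion_count_table")
  }
  model <- match.arg(model)
  counts <- table$counts
  junction_totals <- counts %>%
    group_by(.data$junction) %>%
    summarise(total = sum(.data$unambiguous), .groups = "drop")
  tot <- setNames(junction_totals$total, junction_totals$junction)
  unamb <- counts
  clamped <- 0L

  other_base_mean <- function(j, b) {
    x <- unamb$unambiguous[unamb$junction == j & unamb$base != b]
    mean(x)
  }
  proportional <- function(js, amount) {
    w <- tot[as.character(js)]
    if (sum(w) == 0) w <- rep(1, length(js))
    amount * w / sum(w)
  }

  redis <- tidyr::expand_grid(junction = table$junction_range,
                              base = DNA_BASES) %>%
    mutate(redistributed = 0)
  add <- function(redis, js, b, amounts) {
    idx <- match(paste(js, b), paste(redis$junction, redis$base))
    redis$redistributed[idx] <- redis$redistributed[idx] + amounts
    redis
  }

  for (i in seq_len(nrow(table$windows))) {
    w <- table$windows[i, ]
    js <- w$junctions[[1]]
    b <- w$base
    cnt <- w$count
    if (model == "blunt") {
      redis <- add(redis, js, b, proportional(js, cnt))
    } else if (model == "staggered") {
      likely <- vapply(js, function(j) {
        downstream_base(table$ntdna, table$pam_start, j) == b
      }, logical(1))
      if (!any(likely)) { # degenerate clipped window: fall back to blunt
        redis <- add(redis, js, b, proportional(js, cnt))
        next
      }
      means <- vapply(js[!likely], other_base_mean, numeric(1), b = b)
      remainder <- cnt - sum(means)
      if (remainder < 0) {
        clamped <- clamped + 1L
        remainder <- 0
      }
      if (length(means)) redis <- add(redis, js[!likely], b, means)
      redis <- add(redis, js[likely], b, proportional(js[likely], remainder))
    } else { # combined
      has4 <- 4L %in% js
      likely4 <- has4 &&
        downstream_base(table$ntdna, table$pam_start, 4L) == b
      if (likely4) {
        # the staggered site attracts the window: every other junction gets
        # its template-independent estimate (other-base mean), 4|5 the rest
        rest <- setdiff(js, 4L)
        means <- vapply(rest, other_base_mean, numeric(1), b = b)
        remainder <- cnt - sum(means)
        if (remainder < 0) {
          clamped <- clamped + 1L
          remainder <- 0
        }
        if (length(rest)) redis <- add(redis, rest, b, means)
        redis <- add(redis, 4L, b, remainder)
      } else if (has4) {
        # template-unlikely staggered site: other-base mean at 4|5, the
        # rest spread proportionally (blunt-style) over the other junctions
        m4 <- other_base_mean(4L, b)
        remainder <- cnt - m4
        if (remainder < 0) {
          clamped <- clamped + 1L
          remainder <- 0
        }
        redis <- add(redis, 4L, b, m4)
        rest <- setdiff(js, 4L)
        if (length(rest)) {
          redis <- add(redis, rest, b, proportional(rest, remainder))
        }
      } else {
        redis <- add(redis, js, b, proportional(js, cnt))
      }
    }
  }
  if (clamped > 0L) {
    warn(sprintf("staggered remainder clamped to zero in %d window(s)",
                 clamped))
  }
  out <- counts %>%
    left_join(redis, by = c("junction", "base")) %>%
    mutate(count = .data$unambiguous + .data$redistributed)
  attr(out, "clamped") <- clamped
  attr(out, "model") <- model
  out
}

#' Model-expected 1-bp insertion profile
#'
#' The qualitative per-junction, per-base expectation of each cleavage
#' model: blunt cleavage at 3|4 yields template-independent insertions
#' (uniform over the four bases at 3|4); staggered cleavage with a 1-nt 5'
#' overhang yields template-dependent fill-in (all mass on the base equal to
#' ntDNA nucleotide 4, at 4|5); the combined model carries both signatures
#' (displayed with equal halves - the mixture fraction is deliberately not
#' quantified).
#'
#' @param model `"blunt"`, `"staggered"` or `"combined"`.
#' @param ntdna ntDNA sequence containing protospacer + PAM.
#' @param pam_start 1-based index of the first PAM base.
#' @return tibble with `junction`, `base`, `weight` (weights sum to 1).
#' @export
expected_profile <- function(model = c("blunt", "staggered", "combined"),
                             ntdna, pam_start) {
  model <- match.arg(model)
  base4 <- ntdna_base_at(ntdna, pam_start, 4L)
  blunt <- tibble(junction = 3L, base = DNA_BASES, weight = 0.25)
  stag <- tibble(junction = 4L, base = base4, weight = 1)
  switch(model,
    blunt = blunt,
    staggered = stag,
    combined = bind_rows(blunt %>% mutate(weight = .data$weight / 2),
                         stag %>% mutate(weight = .data$weight / 2)))
}

#' Concordance of redistributed counts with a model signature
#'
#' Per junction: the modal inserted base and its share, and a chi-squared
#' uniformity test over the four bases; junctions are flagged concordant
#' with the blunt signature (uniform bases at 3|4) or the staggered
#' signature (modal base equal to ntDNA nucleotide 4 at 4|5). This
#' describes goodness of fit only - it does not estimate the blunt:staggered
#' mixture fraction, which re-cleavage bias leaves unidentifiable.
#'
#' @param redistributed output of [redistribute_counts()].
#' @param ntdna,pam_start target context (as in [expected_profile()]).
#' @param alpha significance level for the uniformity test (default 0.05).
#' @param modal_min minimal modal share to call a staggered signature
#'   (default 0.5).
#' @return tibble with `junction`, `total`, `modal_base`, `modal_share`,
#'   `uniform_p`, `concordant_blunt`, `concordant_staggered`.
#' @export
model_concordance <- function(redistributed, ntdna, pam_start,
                              alpha = 0.05, modal_min = 0.5) {
  base4 <- ntdna_base_at(ntdna, pam_start, 4L)
  redistributed %>%
    group_by(.data$junction) %>%
    dplyr::group_modify(function(df, key) {
      total <- sum(df$count)
      if (total == 0) return(tibble())
      modal <- df$base[which.max(df$count)]
      share <- max(df$count) / total
      p <- suppressWarnings(chisq.test(df$count)$p.value)
      tibble(total = total, modal_base = modal, modal_share = share,
             uniform_p = p,
             concordant_blunt = key$junction == 3L && p > alpha,
             concordant_staggered = key$junction == 4L &&
               modal == base4 && share >= modal_min)
    }) %>%
    ungroup()
}

#' Construct an insertion count table from components
#'
#' Programmatic constructor for pre-tallied counts (e.g. read back from TSV
#' or built in tests): unambiguous per-junction, per-base counts plus
#' ambiguous windows with accumulated counts.
#'
#' @param counts tibble with `junction`, `base`, `unambiguous`.
#' @param windows tibble with `window_id`, `base`, `junctions`
#'   (list-column of integer vectors), `count`.
#' @param ntdna,pam_start target context.
#' @param junctions junction analysis range.
#' @return an `insertion_count_table`.
#' @export
as_insertion_count_table <- function(counts, windows, ntdna, pam_start,
                                     junctions = 0:8) {
  full <- tidyr::expand_grid(junction = junctions, base = DNA_BASES) %>%
    left_join(counts, by = c("junction", "base")) %>%
    mutate(unambiguous = tidyr::replace_na(.data$unambiguous, 0))
  if (any(full$unambiguous < 0) ||
      (nrow(windows) && any(windows$count < 0))) {
    abort("counts must be non-negative")
  }
  structure(
    list(counts = full, windows = windows, ntdna = ntdna,
         pam_start = pam_start, junction_range = junctions),
    class = "insertion_count_table")
}

#' Write / read an insertion count table as TSV
#'
#' Long format with columns `junction` (label like "3|4"), `base`, `count`,
#' `window_id` (empty for unambiguous rows; ambiguous rows repeat the
#' window's total count on each member junction).
#'
#' @param table an [insertion_count_table()].
#' @param path output path.
#' @return `path` invisibly (writer); an `insertion_count_table` (reader
#'   needs `ntdna` and `pam_start` supplied alongside the file).
#' @export
write_insertion_counts <- function(table, path) {
  unamb <- table$counts %>%
    mutate(junction_label = sprintf("%d|%d", .data$junction,
                                    .data$junction + 1L),
           window_id = "", count = .data$unambiguous) %>%
    select("junction_label", "base", "count", "window_id")
  amb <- table$windows %>%
    tidyr::unnest(cols = "junctions") %>%
    mutate(junction_label = sprintf("%d|%d", .data$junctions,
                                    .data$junctions + 1L)) %>%
    select("junction_label", "base", "count", "window_id")
  readr::write_tsv(bind_rows(unamb, amb), path)
  invisible(path)
}

#' @rdname write_insertion_counts
#' @param ntdna,pam_start,junctions context for the reader.
#' @export
read_insertion_counts <- function(path, ntdna, pam_start, junctions = 0:8) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = "ccdc")
  raw$junction <- as.integer(sub("\\|.*$", "", raw$junction_label))
  unamb <- raw %>% filter(is.na(.data$window_id) | .data$window_id == "") %>%
    select("junction", "base", unambiguous = "count")
  amb <- raw %>% filter(!is.na(.data$window_id), .data$window_id != "") %>%
    group_by(.data$window_id, .data$base) %>%
    summarise(junctions = list(sort(.data$junction)),
              count = .data$count[1], .groups = "drop")
  as_insertion_count_table(unamb, amb, ntdna, pam_start, junctions)
}
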