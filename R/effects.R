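#' Regression of mutation frequency between two assays
#'
#' Ordinary least squares of per-IR frequencies in assay `y` on assay `x`
#' over the shared IRs, reporting the slope, intercept, coefficient of
#' determination and the regression F-test p-value. Used to quantify
#' locus-driven reproducibility of mutation frequency across assays.
#'
#' @param profiles profile tibble from [compute_profiles()] covering both
#'   assays.
#' @param assay_x,assay_y assay labels to compare.
#' @param response profile column to regress (default `"mut_freq"`).
#' @return one-row tibble: `assay_x`, `assay_y`, `response`, `slope`,
#'   `intercept`, `r_squared`, `f_p`, `n`.
#' @export
pairwise_assay_regression <- function(profiles, assay_x, assay_y,
                                      response = "mut_freq") {
  wide <- inner_join(
    profiles %>% filter(.data$assay == assay_x) %>%
      select("barcode", x = dplyr::all_of(response)),
    profiles %>% filter(.data$assay == assay_y) %>%
      select("barcode", y = dplyr::all_of(response)),
    by = "barcode")
  if (nrow(wide) < 3L) abort("need at least 3 shared IRs")
  fit <- lm(y ~ x, data = wide)
  sm <- suppressWarnings(summary(fit)) # perfect fits warn harmlessly
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else {
    pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
       lower.tail = FALSE)
  }
  tibble(assay_x = assay_x, assay_y = assay_y, response = response,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared, f_p = p, n = nrow(wide))
}

#' Decompose mutation-frequency variance over design factors
#'
#' Fits a linear model of per-IR mutation frequency on IR locus (barcode),
#' guide RNA, ssODN inclusion, promoter and the locus x guide interaction,
#' and reports eta-squared effect sizes from type-II sums of squares
#' (marginality-respecting: each term is tested against the model containing
#' all terms that do not include it).
#'
#' In the reporter design every locus carries exactly one promoter, so
#' promoter is nested in (aliased with) locus. The decomposition then fits
#' promoter on the between-locus contrast first and attributes the remaining
#' between-locus variation to locus, reporting the aliasing explicitly.
#' Rank deficiency beyond this declared aliasing is an error.
#'
#' @param freq_tbl tibble with columns `barcode`, `guide`, `ssodn`,
#'   `mut_freq` and optionally `promoter` (e.g. from
#'   [simulate_frequency_table()], or a profile table joined to its design).
#' @return an object of class `cas9_effect_fit`: list with `anova` (tibble
#'   of `term`, `sumsq`, `df`, `statistic`, `p_value`, `eta_sq`),
#'   `r_squared`, `residual_share`, `promoter_aliased`, `n`, and the full
#'   `lm` fit.
#' @export
fit_effect_model <- function(freq_tbl) {
  need <- c("barcode", "guide", "ssodn", "mut_freq")
  if (!all(need %in% names(freq_tbl))) {
    abort(sprintf("`freq_tbl` needs columns %s", paste(need, collapse = ", ")))
  }
  df <- freq_tbl %>%
    mutate(locus = factor(.data$barcode),
           guide = factor(.data$guide),
           ssodn = factor(.data$ssodn))
  has_promoter <- "promoter" %in% names(df) &&
    dplyr::n_distinct(df$promoter) > 1L
  if (has_promoter) df$promoter <- factor(df$promoter)

  y <- df$mut_freq
  ss_total <- sum((y - mean(y))^2)
  rss <- function(formula) deviance(lm(formula, data = df))

  # nesting check: promoter aliased with locus when each locus has 1 promoter
  promoter_aliased <- has_promoter &&
    all((df %>% distinct(.data$locus, .data$promoter) %>%
           count(.data$locus) %>% pull("n")) == 1L)
  if (has_promoter && !promoter_aliased) {
    # promoter crossed with locus beyond the declared aliasing would make
    # type-II SS ill-defined for this design
    abort("rank deficiency: promoter varies within locus; confounded factors: promoter, locus")
  }

  g2 <- length(unique(df$guide)) > 1L
  s2 <- length(unique(df$ssodn)) > 1L
  fml <- function(...) {
    rhs <- c(...)
    as.formula(paste("mut_freq ~", if (length(rhs)) {
      paste(rhs, collapse = " + ")
    } else "1"))
  }
  g_t <- if (g2) "guide"
  s_t <- if (s2) "ssodn"
  ix_t <- if (g2) "locus:guide"
  terms <- list()

  # type-II: each term against the model holding every term not containing it
  if (s2) {
    terms$ssodn <- rss(fml("locus", g_t, ix_t)) -
      rss(fml("locus", g_t, ix_t, "ssodn"))
  }
  if (g2) {
    terms$guide <- rss(fml("locus", s_t)) - rss(fml("locus", s_t, "guide"))
    terms$`locus:guide` <- rss(fml("locus", "guide", s_t)) -
      rss(fml("locus", "guide", s_t, "locus:guide"))
  }
  # promoter on the between-locus contrast first; locus takes the remainder
  if (promoter_aliased) {
    terms$promoter <- rss(fml(g_t, s_t)) - rss(fml(g_t, s_t, "promoter"))
    terms$locus <- rss(fml(g_t, s_t, "promoter")) -
      rss(fml(g_t, s_t, "locus"))
  } else {
    terms$locus <- rss(fml(g_t, s_t)) - rss(fml(g_t, s_t, "locus"))
  }

  full <- lm(fml("locus", g_t, s_t, ix_t), data = df)
  rss_full <- deviance(full)
  df_resid <- full$df.residual
  if (df_resid < 1L) {
    abort("saturated design: no residual degrees of freedom")
  }
  ms_resid <- rss_full / df_resid

  term_df <- c(
    ssodn = length(levels(df$ssodn)) - 1L,
    guide = length(levels(df$guide)) - 1L,
    `locus:guide` = (length(levels(df$locus)) - 1L) *
      (length(levels(df$guide)) - 1L),
    promoter = if (promoter_aliased) length(levels(df$promoter)) - 1L else NA_integer_,
    locus = if (promoter_aliased) {
      length(levels(df$locus)) - length(levels(df$promoter))
    } else {
      length(levels(df$locus)) - 1L
    }
  )

  anova_tbl <- tibble(
    term = names(terms),
    sumsq = unlist(terms),
    df = unname(term_df[names(terms)])
  ) %>%
    mutate(
      statistic = (.data$sumsq / .data$df) / ms_resid,
      p_value = pf(.data$statistic, .data$df, df_resid, lower.tail = FALSE),
      eta_sq = .data$sumsq / ss_total
    ) %>%
    arrange(dplyr::desc(.data$eta_sq))

  out <- list(
    anova = anova_tbl,
    r_squared = 1 - rss_full / ss_total,
    residual_share = rss_full / ss_total,
    promoter_aliased = promoter_aliased,
    n = nrow(df),
    fit = full
  )
  class(out) <- "cas9_effect_fit"
  out
}

#' @export
print.cas9_effect_fit <- function(x, ...) {
  cat(sprintf("<cas9_effect_fit> n = %d, R^2 = %.3f (residual share %.3f)\n",
              x$n, x$r_squared, x$residual_share))
  if (x$promoter_aliased) {
    cat("  note: promoter is nested in locus; promoter eta^2 is the\n",
        " between-locus contrast, locus takes the remainder\n", sep = "")
  }
  print(x$anova)
  invisible(x)
}

#' Wilcoxon shift estimate between two frequency vectors
#'
#' Two-tailed Wilcoxon test (signed-rank when `paired`, rank-sum otherwise)
#' with the Hodges-Lehmann location-shift estimate and its 0.95 confidence
#' interval as the effect size.
#'
#' @param a,b numeric vectors (`b` vs `a`; a positive shift means `b` larger).
#'   Paired mode requires equal lengths.
#' @param paired logical.
#' @param conf_level confidence level (default 0.95).
#' @return one-row tibble: `shift`, `conf_low`, `conf_high`, `p_value`,
#'   `method`, `n`.
#' @export
wilcoxon_shift <- function(a, b, paired = FALSE, conf_level = 0.95) {
  if (paired && length(a) != length(b)) {
    abort("paired mode requires equal-length vectors")
  }
  if (paired && all(b - a == 0)) {
    return(tibble(shift = 0, conf_low = 0, conf_high = 0, p_value = 1,
                  method = "Wilcoxon signed rank (degenerate)",
                  n = length(a)))
  }
  wt <- suppressWarnings(
    wilcox.test(b, a, paired = paired, conf.int = TRUE,
                conf.level = conf_level, alternative = "two.sided"))
  tibble(shift = unname(wt$estimate),
         conf_low = wt$conf.int[1], conf_high = wt$conf.int[2],
         p_value = wt$p.value, method = wt$method,
         n = if (paired) length(a) else length(a) + length(b))
}

#' Knock-in to error-insertion ratio, binned by mutation frequency
#'
#' Per IR, the ratio of knock-in to error-based insertion frequency, binned
#' over total mutation frequency with per-bin means and percentile bootstrap
#' confidence intervals. IRs with zero error insertions have no defined
#' ratio and are dropped (their count is reported); empty bins are reported
#' as missing, not zero.
#'
#' @param profiles profile tibble (with ssODN assay rows) from
#'   [compute_profiles()].
#' @param bin_width bin width on the mutation-frequency axis (default 0.1).
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf_level confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return tibble with `bin_mid`, `n`, `mean_ratio`, `conf_low`,
#'   `conf_high`; attribute `"n_dropped_zero_error"` counts IRs dropped for
#'   a zero denominator.
#' @export
knockin_ratio_binned <- function(profiles, bin_width = 0.1, n_boot = 2000L,
                                 conf_level = 0.95, seed = 1L) {
  dat <- profiles %>%
    mutate(ratio = ifelse(.data$error_insertion_freq > 0,
                          .data$knockin_freq / .data$error_insertion_freq,
                          NA_real_))
  n_dropped <- sum(is.na(dat$ratio))
  dat <- dat %>% filter(!is.na(.data$ratio))
  breaks <- seq(0, 1, by = bin_width)
  dat$bin <- cut(dat$mut_freq, breaks, include.lowest = TRUE, right = FALSE)
  alpha <- (1 - conf_level) / 2
  out <- with_seed(seed, {
    purrr::map(levels(dat$bin), function(b) {
      x <- dat$ratio[dat$bin == b]
      i <- match(b, levels(dat$bin))
      mid <- (breaks[i] + breaks[i + 1]) / 2
      if (length(x) == 0L) {
        return(tibble(bin_mid = mid, n = 0L, mean_ratio = NA_real_,
                      conf_low = NA_real_, conf_high = NA_real_))
      }
      boots <- vapply(seq_len(n_boot), function(k) {
        mean(sample(x, length(x), replace = TRUE))
      }, numeric(1))
      tibble(bin_mid = mid, n = length(x), mean_ratio = mean(x),
             conf_low = unname(quantile(boots, alpha)),
             conf_high = unname(quantile(boots, 1 - alpha)))
    }) %>% bind_rows()
  })
  attr(out, "n_dropped_zero_error") <- n_dropped
  out
}
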