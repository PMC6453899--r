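#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the assay design (guides and
#' ssODN inclusion), thresholds, model choice, seeds and the output
#' directory. Input data are either simulated (`source = "simulate"`, the
#' default) or read from files (`source = "files"`, expecting `library_path`
#' and one FASTQ per assay in `reads_paths`).
#'
#' @param out_dir output directory (created if missing).
#' @param seed root seed for all randomness.
#' @param assays tibble with columns `assay`, `guide`, `ssodn` (logical);
#'   defaults to the three disruption assays of the clonal-line design.
#' @param sim a [simulation_config()] used when `source = "simulate"`.
#' @param source `"simulate"` or `"files"`.
#' @param library_path,reads_paths inputs for `source = "files"`;
#'   `reads_paths` is a named character vector keyed by assay label.
#' @param min_coverage per-IR coverage filter (default 30).
#' @param barcode_tolerance Hamming tolerance for barcode matching.
#' @param align [alignment_params()].
#' @param model cleavage model for the redistribution stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            assays = tibble(
                              assay = c("sgRNA1", "sgRNA2", "sgRNA3"),
                              guide = c("sgRNA1", "sgRNA2", "sgRNA3"),
                              ssodn = c(FALSE, FALSE, FALSE)),
                            sim = simulation_config(seed = seed),
                            source = c("simulate", "files"),
                            library_path = NULL,
                            reads_paths = NULL,
                            min_coverage = 30L,
                            barcode_tolerance = 0L,
                            align = alignment_params(),
                            model = c("combined", "blunt", "staggered")) {
  source <- match.arg(source)
  model <- match.arg(model)
  if (source == "files") {
    if (is.null(library_path) || !file.exists(library_path)) {
      abort(sprintf("library file not found: %s",
                    library_path %||% "<missing>"))
    }
    missing <- reads_paths[!file.exists(reads_paths)]
    if (length(missing)) {
      abort(sprintf("reads file(s) not found: %s",
                    paste(missing, collapse = ", ")))
    }
    if (!all(assays$assay %in% names(reads_paths))) {
      abort("`reads_paths` must name one FASTQ per assay")
    }
  }
  if (min_coverage < 1L) abort("`min_coverage` must be >= 1")
  structure(
    list(out_dir = out_dir, seed = seed, assays = assays, sim = sim,
         source = source, library_path = library_path,
         reads_paths = reads_paths, min_coverage = min_coverage,
         barcode_tolerance = barcode_tolerance, align = align,
         model = model),
    class = "pipeline_config")
}

# stage executor with content-addressed caching: results are stored under
# <out_dir>/cache keyed by a hash of the stage name and its inputs, so a
# rerun with unchanged inputs reuses the stored result.
run_stage <- function(name, inputs, fun, cache_dir, log) {
  key <- rlang::hash(list(name, inputs))
  path <- file.path(cache_dir, paste0(name, "-", substr(key, 1, 12), ".rds"))
  if (file.exists(path)) {
    log(sprintf("stage %s: cache hit (%s)", name, basename(path)))
    return(readRDS(path))
  }
  log(sprintf("stage %s: computing", name))
  res <- tryCatch(fun(), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  saveRDS(res, path)
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order - library, per-assay reads,
#' parsing, mutation calling, UID collapse, profiles, effect decomposition
#' (when more than one assay), pairwise assay regressions, and per-assay
#' insertion-count redistribution under the configured cleavage model -
#' writing tab-separated outputs plus a JSON run manifest (config hash,
#' seed, file checksums) under `config$out_dir`. Stage results are cached by
#' input hash, so a rerun with unchanged inputs reuses them.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with `profiles`, `effects` (or NULL),
#'   `regressions`, `redistributed` (named by assay), `parse_stats`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  log <- if (quiet) function(...) invisible() else function(msg) {
    message("[crisprtrip] ", msg)
  }
  guides <- trip_guides()
  ssodn_def <- trip_ssodn()

  library_tbl <- if (config$source == "simulate") {
    run_stage("library", config$sim,
              function() generate_reporter_library(config$sim),
              cache_dir, log)
  } else {
    readr::read_tsv(config$library_path, show_col_types = FALSE)
  }

  per_assay <- purrr::pmap(config$assays, function(assay, guide, ssodn, ...) {
    use_ssodn <- isTRUE(ssodn)
    g <- guides[[guide]]
    if (is.null(g)) abort(sprintf("unknown guide '%s'", guide))
    reads <- if (config$source == "simulate") {
      run_stage(paste0("reads_", assay),
                list(config$sim, guide, use_ssodn),
                function() simulate_cas9_reads(library_tbl, g, config$sim,
                                               with_ssodn = use_ssodn),
                cache_dir, log)$reads
    } else {
      read_fastq(config$reads_paths[[assay]])
    }
    calls <- run_stage(paste0("calls_", assay),
                       list(reads, config$align, config$barcode_tolerance,
                            guide, use_ssodn),
                       function() {
                         parsed <- parse_amplicons(
                           reads, library_tbl,
                           uid_len = config$sim$uid_len,
                           tolerance = config$barcode_tolerance)
                         stats <- attr(parsed, "parse_stats")
                         collapsed <- collapse_uids(call_reads(
                           parsed, library_tbl, g, config$align,
                           ssodn = if (use_ssodn) ssodn_def))
                         list(calls = collapsed, parse_stats = stats)
                       }, cache_dir, log)
    list(assay = assay, guide = guide, ssodn = use_ssodn,
         calls = calls$calls, parse_stats = calls$parse_stats)
  })

  all_calls <- bind_rows(purrr::map(per_assay, function(x) {
    x$calls %>% mutate(assay = x$assay)
  }))
  # per-assay attributes survive via the design table instead
  profiles <- compute_profiles(all_calls, config$min_coverage) %>%
    left_join(config$assays, by = "assay")

  effects <- NULL
  regressions <- NULL
  if (nrow(config$assays) > 1L && nrow(profiles) > 0L) {
    freq_tbl <- profiles %>%
      left_join(library_tbl %>% select("barcode", "promoter"),
                by = "barcode")
    effects <- tryCatch(fit_effect_model(freq_tbl), error = function(e) {
      log(sprintf("effect model skipped: %s", conditionMessage(e)))
      NULL
    })
    pairs <- utils::combn(config$assays$assay, 2, simplify = FALSE)
    regressions <- bind_rows(purrr::map(pairs, function(p) {
      tryCatch(pairwise_assay_regression(profiles, p[1], p[2]),
               error = function(e) NULL)
    }))
  }

  redistributed <- purrr::map(per_assay, function(x) {
    tab <- insertion_count_table(x$calls)
    redistribute_counts(tab, config$model)
  })
  names(redistributed) <- purrr::map_chr(per_assay, "assay")

  # ---- write outputs -------------------------------------------------------
  outs <- character(0)
  wr <- function(df, name) {
    p <- file.path(config$out_dir, name)
    readr::write_tsv(df, p)
    outs <<- c(outs, p)
  }
  wr(library_tbl, "library.tsv")
  wr(profiles, "profiles.tsv")
  if (!is.null(regressions) && nrow(regressions)) {
    wr(regressions, "assay_regressions.tsv")
  }
  if (!is.null(effects)) {
    wr(generics::tidy(effects), "effect_sizes.tsv")
  }
  for (a in names(redistributed)) {
    wr(redistributed[[a]], sprintf("insertion_counts_%s_%s.tsv",
                                   a, config$model))
  }
  parse_stats <- bind_rows(purrr::map(per_assay, function(x) {
    x$parse_stats %>% mutate(assay = x$assay, .before = 1)
  }))
  wr(parse_stats, "parse_stats.tsv")

  manifest <- list(
    package = "crisprtrip",
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    model = config$model,
    files = as.list(tools::md5sum(outs))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  log(sprintf("wrote %d output files to %s", length(outs) + 1L,
              config$out_dir))

  invisible(list(profiles = profiles, effects = effects,
                 regressions = regressions, redistributed = redistributed,
                 parse_stats = parse_stats, manifest = manifest,
                 library = library_tbl,
                 calls = purrr::set_names(purrr::map(per_assay, "calls"),
                                          purrr::map_chr(per_assay, "assay"))))
}

#' Write bundled demonstration fixtures
#'
#' Generates the two reporter designs - a clonal single-promoter line with
#' 36 IRs (three disruption assays) and a smaller multi-promoter pool
#' (sgRNA2 with and without ssODN, sgRNA3 without) - plus a hairpin-capture
#' fixture, all as plain-text files (TSV libraries and truth tables, 4-line
#' FASTQ reads, key-value config), regenerable byte-identically from the
#' recorded seed.
#'
#' @param seed root seed.
#' @param dir target directory.
#' @param n_pool number of pool IRs (default 60, kept small).
#' @param coverage_mean mean reads per IR (default 50).
#' @return (invisibly) named list of written file paths.
#' @export
make_fixtures <- function(seed = 1L, dir = "fixtures", n_pool = 60L,
                          coverage_mean = 50) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  guides <- trip_guides()
  files <- list()
  put <- function(x, sub, name, fastq = FALSE) {
    d <- file.path(dir, sub)
    dir.create(d, showWarnings = FALSE)
    p <- file.path(d, name)
    if (fastq) write_fastq(x, p) else readr::write_tsv(x, p)
    files[[paste(sub, name, sep = "/")]] <<- p
    p
  }
  write_config <- function(cfg, sub, name) {
    d <- file.path(dir, sub)
    dir.create(d, showWarnings = FALSE)
    p <- file.path(d, name)
    flat <- cfg[vapply(cfg, function(x) is.atomic(x) && length(x) == 1L,
                       logical(1))]
    readr::write_lines(sprintf("%s=%s", names(flat),
                               vapply(flat, as.character, character(1))), p)
    files[[paste(sub, name, sep = "/")]] <<- p
    p
  }

  # clonal cell line: 36 PGK-driven IRs, three disruption assays
  cl_cfg <- simulation_config(seed = derive_seed(seed, 1L), n_irs = 36L,
                              promoters = c(PGK = 1),
                              coverage_mean = coverage_mean)
  cl_lib <- generate_reporter_library(cl_cfg)
  put(cl_lib, "cell_line", "library.tsv")
  write_config(cl_cfg, "cell_line", "config.txt")
  for (gn in names(guides)) {
    sim <- simulate_cas9_reads(cl_lib, guides[[gn]], cl_cfg)
    put(sim$reads, "cell_line", sprintf("reads_%s.fastq", gn), fastq = TRUE)
    put(sim$truth, "cell_line", sprintf("truth_%s.tsv", gn))
  }

  # multi-promoter pool: sgRNA2 +/- ssODN, sgRNA3 disruption
  pool_cfg <- simulation_config(seed = derive_seed(seed, 2L),
                                n_irs = n_pool,
                                promoters = trip_pool_promoters(),
                                barcode_len = 18L,
                                coverage_mean = coverage_mean)
  pool_lib <- generate_reporter_library(pool_cfg)
  # fixture contract: all seven promoter labels present; assign them by
  # largest-remainder proportional allocation (deterministic) instead of
  # random draws, which can miss the rarest label at small n
  w <- trip_pool_promoters()
  quota <- floor(w / sum(w) * n_pool)
  rem <- n_pool - sum(quota)
  frac <- w / sum(w) * n_pool - quota
  if (rem > 0) {
    topup <- names(sort(frac, decreasing = TRUE))[seq_len(rem)]
    quota[topup] <- quota[topup] + 1L
  }
  codes <- promoter_index_codes(names(w))
  pool_lib$promoter <- rep(names(quota), quota)
  pool_lib$promoter_index <- unname(codes[pool_lib$promoter])
  put(pool_lib, "pool", "library.tsv")
  write_config(pool_cfg, "pool", "config.txt")
  pool_assays <- list(
    list(label = "sgRNA2", guide = "sgRNA2", ssodn = FALSE),
    list(label = "sgRNA2_ssODN", guide = "sgRNA2", ssodn = TRUE),
    list(label = "sgRNA3", guide = "sgRNA3", ssodn = FALSE))
  for (a in pool_assays) {
    sim <- simulate_cas9_reads(pool_lib, guides[[a$guide]], pool_cfg,
                               with_ssodn = a$ssodn)
    put(sim$reads, "pool", sprintf("reads_%s.fastq", a$label), fastq = TRUE)
    put(sim$truth, "pool", sprintf("truth_%s.tsv", a$label))
  }

  # hairpin-capture fixture on the sgRNA3 context
  v <- ntdna_view(trip_cassette(), guides$sgRNA3)
  hc_cfg <- simulation_config(seed = derive_seed(seed, 3L))
  mixture <- tibble(t_term = c(3L, 3L, 2L), nt_term = c(3L, 4L, 3L),
                    weight = c(0.5, 0.3, 0.2))
  hc <- simulate_hcodes_reads(v$seq, v$pam_start, mixture, n_reads = 500L,
                              config = hc_cfg)
  put(hc$reads, "hcodes", "reads.fastq", fastq = TRUE)
  put(hc$truth, "hcodes", "truth.tsv")
  write_config(hc_cfg, "hcodes", "config.txt")

  invisible(files)
}
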