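#' Read sequences from a FASTA file
#'
#' Multi-line records are supported; sequence IDs are taken up to the first
#' whitespace in the header. Sequences are normalized to the RNA alphabet
#' (T mapped to U, uppercased). Uses Biostrings when installed, with a
#' plain-text reader otherwise.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
    id <- cumsum(hdr)
    ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
    seqs <- vapply(
      split(lines[!hdr], id[!hdr]),
      function(x) paste(x, collapse = ""), character(1)
    )
    names(seqs) <- ids
  }
  normalize_rna(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i] %||% i), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a clone-count TSV
#'
#' Expects tab-separated columns `segment_id`, `clone_barcode` (or
#' `barcode`), `dna_t0`, `rna_t0`, and optionally `dna_t4`, `rna_t4`.
#' Malformed (non-integer or negative) count cells raise an error naming the
#' offending row.
#'
#' @param path Path to the TSV.
#' @return A clone-count tibble with a `barcode` column.
#' @export
read_counts_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  if ("clone_barcode" %in% names(tbl) && !"barcode" %in% names(tbl)) {
    tbl <- dplyr::rename(tbl, barcode = "clone_barcode")
  }
  for (col in intersect(COUNT_COLS, names(tbl))) {
    x <- tbl[[col]]
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(x))) & !is.na(x))[1L]
      stop(sprintf("malformed count in column '%s', line %d of %s",
                   col, (bad %||% 1L) + 1L, path), call. = FALSE)
    }
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad) > 0L) {
      stop(sprintf("malformed count in column '%s', line %d of %s",
                   col, bad[1L] + 1L, path), call. = FALSE)
    }
  }
  check_counts_table(tbl)
  tbl
}

#' Read a segment-annotation TSV
#'
#' Columns: `segment_id`, `transcript_id`, `chromosome`, `role`,
#' `partner_id`, and optionally `sequence` and `gc_fraction`.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_segments_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  need <- c("segment_id", "role")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0L) {
    stop("segments table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("sequence" %in% names(tbl) && !"gc_fraction" %in% names(tbl)) {
    tbl$gc_fraction <- gc_fraction(tbl$sequence)
  }
  tbl
}

#' Write a tibble as TSV with fixed numeric formatting
#'
#' UTF-8, tab-separated, `NA` for missing values, floats at 6 decimals —
#' the on-disk dialect used for all pipeline artifacts, so identical inputs
#' produce byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv6 <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.double), ~ ifelse(is.na(.x), NA, sprintf("%.6f", .x))
  ))
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv6()]
#'
#' Columns whose cells are all plain integers are read as integer, columns
#' of decimal numbers as double, everything else as character — so
#' `write_tsv6(read_tsv6(path))` reproduces `path` byte for byte.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_tsv6 <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA", col_types = readr::cols(.default = "c"))
  for (col in names(raw)) {
    x <- raw[[col]]
    ok <- !is.na(x)
    if (!any(ok)) next
    if (all(grepl("^-?[0-9]+$", x[ok]))) {
      raw[[col]] <- as.integer(x)
    } else if (all(grepl("^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", x[ok]))) {
      raw[[col]] <- as.numeric(x)
    }
  }
  raw
}

#' Annotate segments with ARE and CDE elements
#'
#' Runs the ARE and CDE scanners over a segment table and returns both a
#' BED-like per-element annotation and a per-segment summary.
#'
#' @param segments Tibble with `segment_id` and `sequence` columns.
#' @return A list with `elements` (columns `segment_id`, `start`, `end`,
#'   `element_type` (`ARE`/`CDE`), `score` (effective length or stem
#'   length), `detail` (JSON string of the full match)) and `summary`
#'   (per-segment longest-ARE fields, cluster, total effective length, and
#'   maximum CDE stem).
#' @export
annotate_segments <- function(segments) {
  seqs <- setNames(segments$sequence, segments$segment_id)
  ares <- scan_ares(seqs)
  cdes <- scan_cdes(seqs)
  are_bed <- tibble::tibble(
    segment_id = ares$seq_id,
    start = ares$start,
    end = ares$start + ares$length,
    element_type = "ARE",
    score = ares$effective_length,
    detail = purrr::pmap_chr(
      ares[c("length", "start_registration", "end_registration",
             "effective_length", "naive_pentamer_count", "match")],
      function(...) jsonlite::toJSON(list(...), auto_unbox = TRUE)
    )
  )
  cde_bed <- tibble::tibble(
    segment_id = cdes$seq_id,
    start = cdes$core_start - cdes$stem_length,
    end = cdes$core_start + 9L + cdes$stem_length,
    element_type = "CDE",
    score = cdes$stem_length,
    detail = purrr::pmap_chr(
      cdes[c("core_sequence", "stem_length", "upstream_stem",
             "downstream_stem")],
      function(...) jsonlite::toJSON(list(...), auto_unbox = TRUE)
    )
  )
  elements <- dplyr::arrange(
    dplyr::bind_rows(are_bed, cde_bed), .data$segment_id, .data$start
  )
  summary <- segment_features(segments)
  cde_max <- cdes |>
    dplyr::group_by(segment_id = .data$seq_id) |>
    dplyr::summarise(cde_max_stem = max(.data$stem_length), .groups = "drop")
  summary <- dplyr::left_join(summary, cde_max, by = "segment_id")
  summary$cluster <- as.character(summary$cluster)
  list(elements = elements, summary = summary[
    c("segment_id", "cluster", "are_length", "are_start_registration",
      "are_effective_length", "are_naive_pentamers", "total_effective_length",
      "cde_max_stem")
  ])
}

#' Run the full analysis pipeline on a simulated or on-disk dataset
#'
#' Executes, in order: motif scanning/annotation, clone-count
#' quantification with QC, GC residualization, explainability (b-squared
#' per outcome and fraction explained by cluster), and
#' leave-one-chromosome-out prediction benchmarking, writing every
#' intermediate artifact as TSV/JSON into `out_dir`. Given the same inputs
#' and seed, outputs are byte-identical across runs.
#'
#' @param config Either a [sim_config()] (the dataset is simulated) or a
#'   list with `counts` and `segments` paths to TSV inputs.
#' @param out_dir Output directory (created if needed).
#' @param gc_order Polynomial order for GC residualization, or `"auto"`.
#' @param methods Predictor methods to benchmark.
#' @param outcomes Raw outcomes to benchmark.
#' @param seed Seed for predictor fold randomness (defaults to the sim seed).
#' @return Invisibly, a list with all in-memory results (`segments`,
#'   `activity`, `pairs`, `b2`, `reports`, paths).
#' @export
run_pipeline <- function(config, out_dir,
                         gc_order = 5L,
                         methods = c("ared_plus", "naive_pentamers",
                                     "effective_length", "lasso_kmer"),
                         outcomes = c("steady_state_expression", "stability"),
                         seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)

  if (inherits(config, "sim_config")) {
    sim <- simulate_dataset(config)
    segments <- sim$segments
    counts <- sim$counts
    seed <- seed %||% config$seed
    write_tsv6(sim$truth, file.path(out_dir, "truth.tsv"))
  } else {
    counts <- read_counts_tsv(config$counts)
    segments <- read_segments_tsv(config$segments)
    seed <- seed %||% (config$seed %||% 1L)
  }
  logf("stage scan: %d segments", nrow(segments))

  ann <- annotate_segments(segments)
  write_tsv6(ann$elements, file.path(out_dir, "elements.tsv"))
  write_tsv6(ann$summary, file.path(out_dir, "segment_summary.tsv"))
  logf("stage scan: %d elements annotated", nrow(ann$elements))

  qc <- qc_segments(counts)
  activity <- summarize_segments(counts, qc = qc)
  logf("stage quantify: %d/%d segments pass expression QC, %d pass stability QC",
       sum(qc$pass_expression), nrow(qc), sum(qc$pass_stability %in% TRUE))
  write_tsv6(qc, file.path(out_dir, "qc.tsv"))

  activity <- residualize(activity, segments = segments, order = gc_order)
  fits <- attr(activity, "gc_fits")
  jsonlite::write_json(
    purrr::map(fits, function(f) list(
      outcome = f$outcome, order = f$order,
      coefficients = as.list(f$coefficients),
      loo_r_by_order = as.list(f$loo_r_by_order %||% NULL)
    )),
    file.path(out_dir, "gc_fit.json"), auto_unbox = TRUE, digits = NA
  )
  write_tsv6(activity, file.path(out_dir, "activity.tsv"))
  logf("stage residualize: order(s) %s",
       paste(purrr::map_int(fits, "order"), collapse = ", "))

  have_pairs <- any(segments$role != "reference" & !is.na(segments$partner_id))
  pairs <- NULL
  if (have_pairs) {
    pairs <- pair_delta(activity, segments)
    write_tsv6(pairs, file.path(out_dir, "pair_deltas.tsv"))
    logf("stage quantify: %d mutant/reference pairs", nrow(pairs))
  }

  clones <- clone_activity(counts)
  feat <- segment_features(segments)
  b2 <- list(
    expression = tryCatch(
      explainability(clones, .data$expression, outcome = "expression"),
      error = function(e) NULL),
    stability = tryCatch(
      explainability(clones, .data$stability, outcome = "stability"),
      error = function(e) NULL)
  )
  if (have_pairs) {
    b2$delta_expression <- tryCatch(
      delta_explainability(clones, .data$expression, pairs,
                           outcome = "delta_expression"),
      error = function(e) NULL)
    b2$delta_stability <- tryCatch(
      delta_explainability(clones, .data$stability, pairs,
                           outcome = "delta_stability"),
      error = function(e) NULL)
  }
  b2 <- purrr::compact(b2)
  jsonlite::write_json(
    purrr::map(b2, function(e) list(b2 = e$b2, se = e$se, n_seqs = e$n_seqs)),
    file.path(out_dir, "explainability.json"), auto_unbox = TRUE, digits = NA
  )
  logf("stage explain: %d outcomes", length(b2))

  data <- dplyr::left_join(
    feat,
    activity[c("segment_id", "steady_state_expression", "stability",
               "expression_residual", "stability_residual")],
    by = "segment_id"
  )
  reports <- list()
  for (oc in outcomes) {
    resid_col <- switch(oc,
      steady_state_expression = "expression_residual",
      stability = "stability_residual", oc)
    for (m in methods) {
      rep_id <- paste(m, oc, sep = ".")
      reports[[rep_id]] <- tryCatch(
        loco_cv(data, outcome = resid_col, method = m, seed = seed),
        error = function(e) NULL
      )
    }
  }
  reports <- purrr::compact(reports)
  table2 <- purrr::map_dfr(reports, glance)
  write_tsv6(table2, file.path(out_dir, "predictions.tsv"))
  jsonlite::write_json(
    purrr::map(reports, function(r) list(method = r$method,
                                         outcome = r$outcome,
                                         pooled_r = r$r, n = r$n)),
    file.path(out_dir, "prediction_report.json"), auto_unbox = TRUE,
    digits = NA
  )
  logf("stage predict: %d method x outcome cells", nrow(table2))

  provenance <- list(
    package = "utrmpra",
    version = as.character(utils::packageVersion("utrmpra")),
    seed = seed,
    config_hash = rlang::hash(config),
    n_segments = nrow(segments)
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    segments = segments, activity = activity, pairs = pairs, b2 = b2,
    reports = reports, out_dir = out_dir
  ))
}
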