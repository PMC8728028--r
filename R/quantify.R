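COUNT_COLS <- c("dna_t0", "rna_t0", "dna_t4", "rna_t4")

check_counts_table <- function(counts, require_t4 = FALSE) {
  need <- c("segment_id", "barcode", "dna_t0", "rna_t0")
  if (require_t4) need <- c(need, "dna_t4", "rna_t4")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0L) {
    stop("counts table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(COUNT_COLS, names(counts))) {
    x <- counts[[col]]
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s' has a non-count value in row %d", col, bad[1L]),
           call. = FALSE)
    }
  }
  invisible(counts)
}

#' Normalize clone counts to counts-per-million
#'
#' Scales each raw count column (`dna_t0`, `rna_t0`, `dna_t4`, `rna_t4`) to
#' counts-per-million of that column's total, so the reporter ratios computed
#' downstream are invariant to per-sample sequencing depth. Normalized
#' columns are added with a `_cpm` suffix.
#'
#' @param counts A clone-count tibble with columns `segment_id`, `barcode`,
#'   and the raw count columns.
#' @return The input tibble with `*_cpm` columns appended.
#' @export
normalize_counts <- function(counts) {
  check_counts_table(counts)
  if (nrow(counts) == 0L) stop("empty counts table", call. = FALSE)
  for (col in intersect(COUNT_COLS, names(counts))) {
    tot <- sum(counts[[col]])
    if (tot == 0) stop(sprintf("column '%s' has total 0", col), call. = FALSE)
    counts[[paste0(col, "_cpm")]] <- counts[[col]] / tot * 1e6
  }
  counts
}

#' Per-clone steady-state expression and mRNA stability
#'
#' Computes, for each clone, the reporter ratios
#' \deqn{expression = RNA / (RNA + DNA) |_{t0}}
#' and
#' \deqn{stability = r_4 / (r_4 + r_0)}
#' where \eqn{r_t} is the RNA/(RNA+DNA) ratio at timepoint t. A stability of
#' 0.5 means no decay over the chase interval. Ratios are undefined
#' (returned as `NA`) when their denominator is zero. Because both
#' statistics are ratios of counts from the same clone, they are invariant
#' to scaling all of a clone's counts.
#'
#' @param counts A clone-count tibble; if `use = "cpm"` (default) the
#'   `*_cpm` columns from [normalize_counts()] are used (and computed on the
#'   fly if absent), if `use = "raw"` the raw counts are used.
#' @param use `"cpm"` or `"raw"`.
#' @return The input tibble with `expression` and `stability` columns
#'   appended (and `r0`, `r4` intermediates).
#' @export
clone_activity <- function(counts, use = c("cpm", "raw")) {
  use <- match.arg(use)
  if (use == "cpm" && !all(paste0(COUNT_COLS, "_cpm") %in% names(counts))) {
    counts <- normalize_counts(counts)
  }
  suffix <- if (use == "cpm") "_cpm" else ""
  rna0 <- counts[[paste0("rna_t0", suffix)]]
  dna0 <- counts[[paste0("dna_t0", suffix)]]
  r0 <- ifelse(rna0 + dna0 > 0, rna0 / (rna0 + dna0), NA_real_)
  counts$r0 <- r0
  counts$expression <- r0
  has_t4 <- all(c("rna_t4", "dna_t4") %in% names(counts))
  if (has_t4) {
    rna4 <- counts[[paste0("rna_t4", suffix)]]
    dna4 <- counts[[paste0("dna_t4", suffix)]]
    r4 <- ifelse(rna4 + dna4 > 0, rna4 / (rna4 + dna4), NA_real_)
    counts$r4 <- r4
    counts$stability <- ifelse(
      !is.na(r4) & !is.na(r0) & (r4 + r0) > 0, r4 / (r4 + r0), NA_real_
    )
  }
  counts
}

#' Quality-control filter for segments
#'
#' A segment's measurements are kept only if it is represented by at least
#' `min_clones` clones with more than `min_dna` raw DNA counts each
#' (strictly greater), and at least one clone has at least one RNA count.
#' The DNA and RNA conditions are applied per analysis timepoint: the t0
#' columns gate the expression estimate, and both t0 and t4 gate the
#' stability estimate.
#'
#' @param counts Raw clone-count tibble.
#' @param min_clones Minimum number of high-DNA clones.
#' @param min_dna DNA count that a clone must strictly exceed.
#' @return A tibble with one row per segment: `segment_id`,
#'   `pass_expression`, `pass_stability`, and failure `reason` columns.
#' @export
qc_segments <- function(counts, min_clones = 5L, min_dna = 5L) {
  check_counts_table(counts)
  has_t4 <- all(c("rna_t4", "dna_t4") %in% names(counts))
  out <- counts |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      dna_ok_t0 = sum(.data$dna_t0 > min_dna) >= min_clones,
      rna_ok_t0 = any(.data$rna_t0 >= 1),
      dna_ok_t4 = if (has_t4) sum(.data$dna_t4 > min_dna) >= min_clones else NA,
      rna_ok_t4 = if (has_t4) any(.data$rna_t4 >= 1) else NA,
      .groups = "drop"
    )
  out$pass_expression <- out$dna_ok_t0 & out$rna_ok_t0
  out$pass_stability <- if (has_t4) {
    out$pass_expression & out$dna_ok_t4 & out$rna_ok_t4
  } else NA
  reason_of <- function(dna0, rna0, dna4, rna4) {
    if (!dna0) return(sprintf("fewer than %d clones with DNA > %d at t0", min_clones, min_dna))
    if (!rna0) return("no clone with RNA >= 1 at t0")
    if (!is.na(dna4) && !dna4) return(sprintf("fewer than %d clones with DNA > %d at t4", min_clones, min_dna))
    if (!is.na(rna4) && !rna4) return("no clone with RNA >= 1 at t4")
    NA_character_
  }
  out$reason <- purrr::pmap_chr(
    out[c("dna_ok_t0", "rna_ok_t0", "dna_ok_t4", "rna_ok_t4")],
    function(dna_ok_t0, rna_ok_t0, dna_ok_t4, rna_ok_t4)
      reason_of(dna_ok_t0, rna_ok_t0, dna_ok_t4, rna_ok_t4)
  )
  out[c("segment_id", "n_clones", "pass_expression", "pass_stability", "reason")]
}

#' Aggregate clone activities to segment-level estimates
#'
#' Segment steady-state expression and stability are the unweighted means of
#' the defined clone-level values. Segments failing the QC filter for an
#' outcome get `NA` for that outcome.
#'
#' @param counts Raw clone-count tibble (normalization and clone ratios are
#'   computed internally unless `expression`/`stability` columns are already
#'   present).
#' @param qc Optional output of [qc_segments()]; computed from `counts` if
#'   `NULL`. Pass `FALSE` to skip QC gating.
#' @param use Passed to [clone_activity()].
#' @param aggregate `"mean_ratio"` (default): compute the ratios per clone,
#'   then average across clones — this keeps clone-level values available
#'   for the variance decomposition. `"pooled"`: sum counts across a
#'   segment's clones first, then form the ratios once.
#' @return A tibble with one row per segment: `segment_id`, `n_clones`,
#'   `n_expression` / `n_stability` (clones with defined values),
#'   `steady_state_expression`, `stability`, `pass_expression`,
#'   `pass_stability`, and empty residual columns to be filled by
#'   [residualize()].
#' @export
summarize_segments <- function(counts, qc = NULL, use = "cpm",
                               aggregate = c("mean_ratio", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (!all(c("expression", "stability") %in% names(counts))) {
    counts <- clone_activity(counts, use = use)
  }
  gate <- !isFALSE(qc)
  if (gate && is.null(qc)) qc <- qc_segments(counts)
  has_stab <- "stability" %in% names(counts)
  if (aggregate == "pooled") {
    suffix <- if (use == "cpm") "_cpm" else ""
    pooled <- counts |>
      dplyr::group_by(.data$segment_id) |>
      dplyr::summarise(
        dna_t0 = sum(.data[[paste0("dna_t0", suffix)]]),
        rna_t0 = sum(.data[[paste0("rna_t0", suffix)]]),
        dna_t4 = if (has_stab) sum(.data[[paste0("dna_t4", suffix)]]) else NA_real_,
        rna_t4 = if (has_stab) sum(.data[[paste0("rna_t4", suffix)]]) else NA_real_,
        .groups = "drop"
      )
    r0 <- with(pooled, ifelse(rna_t0 + dna_t0 > 0,
                              rna_t0 / (rna_t0 + dna_t0), NA_real_))
    r4 <- with(pooled, ifelse(!is.na(rna_t4) & rna_t4 + dna_t4 > 0,
                              rna_t4 / (rna_t4 + dna_t4), NA_real_))
    pooled_act <- tibble::tibble(
      segment_id = pooled$segment_id,
      pooled_expression = r0,
      pooled_stability = ifelse(!is.na(r4) & !is.na(r0) & r4 + r0 > 0,
                                r4 / (r4 + r0), NA_real_)
    )
  }
  act <- counts |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      n_expression = sum(!is.na(.data$expression)),
      n_stability = if (has_stab) sum(!is.na(.data$stability)) else 0L,
      steady_state_expression = mean(.data$expression, na.rm = TRUE),
      stability = if (has_stab) mean(.data$stability, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  if (aggregate == "pooled") {
    act$steady_state_expression <-
      pooled_act$pooled_expression[match(act$segment_id,
                                         pooled_act$segment_id)]
    act$stability <-
      pooled_act$pooled_stability[match(act$segment_id,
                                        pooled_act$segment_id)]
    act$n_expression <- ifelse(is.na(act$steady_state_expression), 0L,
                               act$n_clones)
    act$n_stability <- ifelse(is.na(act$stability), 0L, act$n_clones)
  }
  act$steady_state_expression[act$n_expression == 0L] <- NA_real_
  act$stability[act$n_stability == 0L] <- NA_real_
  if (gate) {
    act <- dplyr::left_join(
      act, qc[c("segment_id", "pass_expression", "pass_stability")],
      by = "segment_id"
    )
    act$steady_state_expression[!act$pass_expression %in% TRUE] <- NA_real_
    if (!all(is.na(act$pass_stability))) {
      act$stability[!act$pass_stability %in% TRUE] <- NA_real_
    }
  } else {
    act$pass_expression <- act$n_expression > 0L
    act$pass_stability <- act$n_stability > 0L
  }
  dropped <- act$segment_id[act$n_expression == 0L]
  if (length(dropped) > 0L) {
    message(length(dropped), " segment(s) dropped: no defined clone values")
  }
  act$expression_residual <- NA_real_
  act$stability_residual <- NA_real_
  act
}

#' Mutant minus reference effects for designed pairs
#'
#' For every mutant segment with a valid reference partner, computes
#' \eqn{\Delta = mutant - reference} for expression and stability, on the
#' GC-residualized values when [residualize()] has filled them (or when
#' `values = "residual"`), otherwise on the raw segment estimates. The
#' number of nucleotide differences between the paired sequences is recorded
#' when sequences are available.
#'
#' @param activity Segment-level activity tibble from [summarize_segments()].
#' @param segments Segment annotation tibble with `segment_id`, `role`,
#'   `partner_id` (and optionally `sequence`, `chromosome`).
#' @param values `"auto"` (residuals if filled), `"raw"`, or `"residual"`.
#' @return A tibble with one row per QC-passing pair: `mutant_id`,
#'   `reference_id`, `role`, `chromosome`, `delta_expression`,
#'   `delta_stability`, `n_mutated_nt`.
#' @export
pair_delta <- function(activity, segments,
                       values = c("auto", "raw", "residual")) {
  values <- match.arg(values)
  muts <- segments[!is.na(segments$partner_id) & segments$role != "reference", ]
  if (nrow(muts) == 0L) stop("no mutant segments with partners", call. = FALSE)
  if (!all(muts$partner_id %in% segments$segment_id)) {
    stop("some mutants reference a missing partner segment", call. = FALSE)
  }
  use_resid <- switch(values,
    raw = FALSE,
    residual = TRUE,
    auto = any(!is.na(activity$expression_residual)) ||
      any(!is.na(activity$stability_residual))
  )
  ecol <- if (use_resid) "expression_residual" else "steady_state_expression"
  scol <- if (use_resid) "stability_residual" else "stability"
  a <- activity[c("segment_id", ecol, scol)]
  names(a) <- c("segment_id", "e", "s")
  out <- tibble::tibble(
    mutant_id = muts$segment_id,
    reference_id = muts$partner_id,
    role = muts$role,
    chromosome = if ("chromosome" %in% names(muts)) muts$chromosome else NA_character_
  )
  m <- dplyr::left_join(out, a, by = c(mutant_id = "segment_id"))
  r <- dplyr::left_join(out, a, by = c(reference_id = "segment_id"))
  out$delta_expression <- m$e - r$e
  out$delta_stability <- m$s - r$s
  if ("sequence" %in% names(segments)) {
    seqs <- setNames(segments$sequence, segments$segment_id)
    out$n_mutated_nt <- purrr::map2_int(
      out$mutant_id, out$reference_id,
      function(mi, ri) {
        a <- strsplit(seqs[[mi]], "")[[1]]
        b <- strsplit(seqs[[ri]], "")[[1]]
        if (length(a) != length(b)) return(NA_integer_)
        sum(a != b)
      }
    )
  } else {
    out$n_mutated_nt <- NA_integer_
  }
  out
}

#' Per-nucleotide effect of a mutation
#'
#' Divides an activity change by the number of mutated nucleotides, the
#' yardstick used to compare the strength of regulatory elements (e.g. a
#' stability change of 0.158 from mutating the 3 central U's of a
#' three-pentamer ARE is 0.053 per nucleotide).
#'
#' @param delta Numeric vector of activity changes.
#' @param n_nt Integer vector of mutated nucleotide counts (>= 1).
#' @return `delta / n_nt`.
#' @export
per_nucleotide_effect <- function(delta, n_nt) {
  if (any(n_nt < 1, na.rm = TRUE)) {
    stop("n_nt must be at least 1", call. = FALSE)
  }
  delta / n_nt
}
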