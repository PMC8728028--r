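#' Technical variance of segment means from clone-to-clone spread
#'
#' The premise of the explainability analysis is that technical variation
#' between sequence segments can be estimated from variation between clones
#' of the same segment. Each segment mean's sampling variance is the
#' within-segment clone variance divided by the number of clones; the
#' technical variance of the dataset is the average of these over segments.
#'
#' @param data Clone-level tibble.
#' @param value Column holding the clone-level measure (tidy-eval).
#' @param segment Column identifying segments (tidy-eval).
#' @return The estimated technical variance (a scalar).
#' @export
technical_variance <- function(data, value, segment = segment_id) {
  sv <- segment_sampling_stats(
    data, {{ value }}, {{ segment }}
  )
  mean(sv$sampling_var)
}

#' Per-segment means and sampling variances
#'
#' @inheritParams technical_variance
#' @return A tibble with `segment_id`, `mean`, `sampling_var`
#'   (clone variance / n), and `n_clones`. Segments with fewer than two
#'   defined clone values are dropped (their sampling variance cannot be
#'   estimated).
#' @export
segment_sampling_stats <- function(data, value, segment = segment_id) {
  out <- data |>
    dplyr::group_by(segment_id = {{ segment }}) |>
    dplyr::summarise(
      mean = mean({{ value }}, na.rm = TRUE),
      sampling_var = stats::var({{ value }}[!is.na({{ value }})]) /
        sum(!is.na({{ value }})),
      n_clones = sum(!is.na({{ value }})),
      .groups = "drop"
    )
  out <- out[out$n_clones >= 2L & is.finite(out$sampling_var), ]
  if (nrow(out) == 0L) {
    stop("no segment has two or more clones with defined values", call. = FALSE)
  }
  out
}

#' Explainability b-squared of a set of segment measurements
#'
#' Estimates the fraction of between-segment variance attributable to
#' sequence rather than clone-level technical noise:
#' \deqn{b^2 = (total - technical) / total}
#' where *total* is the variance of segment means and *technical* is the
#' mean sampling variance of those means ([technical_variance()]). b-squared
#' near 0 means technical variance accounts for all variation; near 1,
#' sequence differences dominate. Small-sample estimates can be slightly
#' negative; they are reported as-is (with a warning), not clipped. The
#' standard error is a leave-one-segment-out jackknife.
#'
#' @param values Numeric vector of segment-level means (one per sequence),
#'   or pair deltas for mutation outcomes.
#' @param sampling_vars Numeric vector of each value's sampling variance
#'   (for a pair delta: the sum of the two members' sampling variances).
#'   Alternatively supply a scalar `technical`.
#' @param technical Optional scalar technical variance; ignored when
#'   `sampling_vars` is given.
#' @param outcome Optional label stored in the result.
#' @return An object of class `b2_estimate`: `b2`, `se`, `n_seqs`,
#'   `total`, `technical`, `outcome`. Supports `tidy()` and `glance()`.
#' @export
b_squared <- function(values, sampling_vars = NULL, technical = NULL,
                      outcome = NULL) {
  keep <- !is.na(values)
  if (!is.null(sampling_vars)) keep <- keep & !is.na(sampling_vars)
  values <- values[keep]
  if (!is.null(sampling_vars)) sampling_vars <- sampling_vars[keep]
  n <- length(values)
  if (n < 3L) stop("need at least 3 segments", call. = FALSE)
  if (is.null(sampling_vars) && is.null(technical)) {
    stop("supply sampling_vars or technical", call. = FALSE)
  }
  tech <- if (!is.null(sampling_vars)) mean(sampling_vars) else technical
  if (tech < 0) stop("technical variance must be nonnegative", call. = FALSE)
  total <- stats::var(values)
  if (total == 0) stop("zero total variance across segments", call. = FALSE)
  b2 <- (total - tech) / total

  # Jackknife over segments, vectorized with leave-one-out identities.
  ybar <- mean(values)
  ss <- sum((values - ybar)^2)
  ss_i <- ss - (n / (n - 1)) * (values - ybar)^2
  total_i <- ss_i / (n - 2)
  tech_i <- if (!is.null(sampling_vars)) {
    (n * tech - sampling_vars) / (n - 1)
  } else rep(tech, n)
  b2_i <- (total_i - tech_i) / total_i
  se <- sqrt((n - 1) / n * sum((b2_i - mean(b2_i))^2))

  if (b2 < 0) {
    warning("b-squared estimate is negative (technical exceeds total variance)",
            call. = FALSE)
  }
  structure(
    list(b2 = b2, se = se, n_seqs = n, total = total, technical = tech,
         outcome = outcome),
    class = "b2_estimate"
  )
}

#' @export
print.b2_estimate <- function(x, ...) {
  cat(sprintf("<b2_estimate>%s b2 = %.4f +/- %.4f (n_seqs = %d)\n",
              if (is.null(x$outcome)) "" else paste0(" ", x$outcome, ":"),
              x$b2, x$se, x$n_seqs))
  invisible(x)
}

#' @rdname b2_tidiers
#' @export
tidy.b2_estimate <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome %||% NA_character_,
    b2 = x$b2, se = x$se, n_seqs = x$n_seqs
  )
}

#' Tidy explainability estimates
#'
#' @param x A `b2_estimate`.
#' @param ... Unused.
#' @name b2_tidiers
#' @export
glance.b2_estimate <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome %||% NA_character_,
    b2 = x$b2, se = x$se, n_seqs = x$n_seqs,
    total_variance = x$total, technical_variance = x$technical
  )
}

#' Explainability from clone-level data in one step
#'
#' Convenience wrapper: computes per-segment means and sampling variances
#' with [segment_sampling_stats()] and passes them to [b_squared()].
#'
#' @inheritParams technical_variance
#' @param outcome Optional label stored in the result.
#' @return A `b2_estimate`.
#' @export
explainability <- function(data, value, segment = segment_id, outcome = NULL) {
  sv <- segment_sampling_stats(data, {{ value }}, {{ segment }})
  b_squared(sv$mean, sv$sampling_var, outcome = outcome)
}

#' Explainability of mutation effects (pair deltas)
#'
#' For mutant/reference pairs the measured quantity is
#' \eqn{\Delta = mutant - reference}; its technical (sampling) variance is
#' the sum of the two members' sampling variances, assuming independence.
#'
#' @inheritParams technical_variance
#' @param pairs Tibble with `mutant_id` and `reference_id` columns naming
#'   segments present in `data`.
#' @param outcome Optional label.
#' @return A `b2_estimate` over pairs.
#' @export
delta_explainability <- function(data, value, pairs, segment = segment_id,
                                 outcome = NULL) {
  sv <- segment_sampling_stats(data, {{ value }}, {{ segment }})
  m <- match(pairs$mutant_id, sv$segment_id)
  r <- match(pairs$reference_id, sv$segment_id)
  keep <- !is.na(m) & !is.na(r)
  b_squared(
    sv$mean[m[keep]] - sv$mean[r[keep]],
    sv$sampling_var[m[keep]] + sv$sampling_var[r[keep]],
    outcome = outcome
  )
}

#' Fraction of sequence-driven variance explained by a grouping
#'
#' Compares the explainability of the full set of values with the
#' explainability that remains after centring values within groups (a
#' candidate classification of the sequences): first b-squared is computed
#' for the whole dataset ignoring groups, then on within-group deviations
#' (pooled, with degrees of freedom corrected for the number of groups) with
#' the same technical variance, and the fraction explained by the grouping
#' is
#' \deqn{(b^2_{total} - b^2_{groups}) / b^2_{total}.}
#' A perfect grouping removes all sequence-driven variance within groups
#' (fraction 1); an uninformative grouping leaves it unchanged (fraction 0).
#'
#' @param values Segment-level values (or pair deltas).
#' @param sampling_vars Per-value sampling variances.
#' @param groups Group labels, same length as `values`.
#' @return A list of class `group_fraction`: `fraction`, `se` (jackknife
#'   over segments), `b2_total`, `b2_groups`, `n_seqs`, `n_groups`.
#' @export
fraction_explained_by_groups <- function(values, sampling_vars, groups) {
  keep <- !is.na(values) & !is.na(sampling_vars) & !is.na(groups)
  values <- values[keep]
  sampling_vars <- sampling_vars[keep]
  groups <- as.character(groups)[keep]
  if (length(unique(groups)) < 2L) {
    warning("degenerate grouping (single group); fraction is 0", call. = FALSE)
    return(structure(
      list(fraction = 0, se = NA_real_, b2_total = NA_real_,
           b2_groups = NA_real_, n_seqs = length(values), n_groups = 1L),
      class = "group_fraction"
    ))
  }
  est <- group_fraction_point(values, sampling_vars, groups)
  n <- length(values)
  jk <- vapply(seq_len(n), function(i) {
    group_fraction_point(values[-i], sampling_vars[-i], groups[-i])$fraction
  }, double(1))
  jk <- jk[is.finite(jk)]
  se <- if (length(jk) > 1L) {
    sqrt((length(jk) - 1) / length(jk) * sum((jk - mean(jk))^2))
  } else NA_real_
  structure(
    c(est, list(se = se, n_seqs = n, n_groups = length(unique(groups)))),
    class = "group_fraction"
  )
}

group_fraction_point <- function(values, sampling_vars, groups) {
  n <- length(values)
  tech <- mean(sampling_vars)
  total <- stats::var(values)
  b2_total <- (total - tech) / total
  gmean <- stats::ave(values, groups)
  dev <- values - gmean
  df <- n - length(unique(groups))
  within <- if (df > 0L) sum(dev^2) / df else 0
  b2_groups <- if (within > 0) (within - tech) / within else 0
  list(
    fraction = (b2_total - b2_groups) / b2_total,
    b2_total = b2_total,
    b2_groups = b2_groups
  )
}

#' @export
print.group_fraction <- function(x, ...) {
  cat(sprintf(
    "<group_fraction> fraction = %.3f +/- %.3f (b2 total %.3f, within groups %.3f; %d seqs, %d groups)\n",
    x$fraction, x$se, x$b2_total, x$b2_groups, x$n_seqs, x$n_groups
  ))
  invisible(x)
}

#' @export
tidy.group_fraction <- function(x, ...) {
  tibble::tibble(
    fraction = x$fraction, se = x$se,
    b2_total = x$b2_total, b2_groups = x$b2_groups,
    n_seqs = x$n_seqs, n_groups = x$n_groups
  )
}
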