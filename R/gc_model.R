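#' Fit a polynomial GC-content trend
#'
#' Fits an order-N least-squares polynomial of an activity measure on GC
#' fraction. GC content confounds reporter measurements (GC-rich segments
#' express less), so the fitted trend is subtracted from the raw values
#' before motif-level analyses. The fit uses an orthogonal polynomial basis
#' internally for numerical conditioning; coefficients are reported in the
#' monomial basis.
#'
#' @param data A data frame of per-segment values.
#' @param outcome Column holding the activity measure (tidy-eval).
#' @param gc Column holding GC fractions in \[0, 1\] (tidy-eval).
#' @param order Polynomial order N (1-7), or `"auto"` to select by
#'   leave-one-out cross-validation via [select_gc_order()].
#' @param tol Tolerance passed to [select_gc_order()] when `order = "auto"`.
#' @return An object of class `gc_fit` with elements `outcome`, `order`,
#'   `coefficients` (monomial, intercept first), `loo_r_by_order` (when
#'   order was selected automatically), and `n`. Supports `predict()`,
#'   `tidy()`, `glance()`, and `autoplot()`.
#' @examples
#' d <- data.frame(gc = runif(50), y = rnorm(50))
#' fit <- fit_gc_polynomial(d, y, gc, order = 2)
#' @export
fit_gc_polynomial <- function(data, outcome, gc = gc_fraction, order = 5L,
                              tol = 0.002) {
  y <- rlang::eval_tidy(rlang::enquo(outcome), data)
  x <- rlang::eval_tidy(rlang::enquo(gc), data)
  outcome_name <- rlang::as_label(rlang::enquo(outcome))
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  if (any(x < 0 | x > 1)) stop("gc fractions must lie in [0, 1]", call. = FALSE)
  loo <- NULL
  if (identical(order, "auto")) {
    sel <- select_gc_order_xy(y, x, orders = 1:7, tol = tol)
    order <- sel$order
    loo <- sel$loo_r_by_order
  }
  order <- as.integer(order)
  if (order < 1L || order > 7L) stop("order must be in 1..7", call. = FALSE)
  if (length(y) < order + 2L) {
    stop("need at least order + 2 observations", call. = FALSE)
  }
  if (length(unique(x)) <= order) {
    stop("rank-deficient fit: fewer distinct gc values than order + 1",
         call. = FALSE)
  }
  model <- stats::lm(y ~ stats::poly(x, order))
  structure(
    list(
      outcome = outcome_name,
      order = order,
      coefficients = monomial_coefs(model, order, range(x)),
      loo_r_by_order = loo,
      n = length(y),
      model = model,
      gc_range = range(x)
    ),
    class = "gc_fit"
  )
}

# Convert an orthogonal-basis polynomial lm to monomial coefficients by
# exact interpolation at order + 1 distinct nodes.
monomial_coefs <- function(model, order, rng) {
  nodes <- seq(rng[1], rng[2], length.out = order + 1L)
  if (order == 0L) nodes <- rng[1]
  v <- outer(nodes, 0:order, `^`)
  fitted <- as.numeric(stats::predict(model, newdata = list(x = nodes)))
  setNames(solve(v, fitted), paste0("gc^", 0:order))
}

#' @export
predict.gc_fit <- function(object, gc, ...) {
  polyval(object$coefficients, gc)
}

#' @export
print.gc_fit <- function(x, ...) {
  cat(sprintf("<gc_fit> outcome: %s, order: %d, n = %d\n",
              x$outcome, x$order, x$n))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Select the GC polynomial order by leave-one-out cross-validation
#'
#' For each candidate order, computes the leave-one-out predicted values in
#' closed form (via the hat-matrix diagonal) and the Pearson correlation
#' between LOO predictions and observed values, then returns the smallest
#' order whose LOO r is within `tol` of the best. Prediction accuracy
#' typically plateaus around order 5 on reporter data.
#'
#' @inheritParams fit_gc_polynomial
#' @param orders Candidate orders.
#' @param tol How close to the maximum LOO r an order must be to count as
#'   "not significantly worse".
#' @return The selected order (integer) with attribute `loo_r` holding the
#'   per-order LOO Pearson correlations.
#' @export
select_gc_order <- function(data, outcome, gc = gc_fraction, orders = 1:7,
                            tol = 0.002) {
  y <- rlang::eval_tidy(rlang::enquo(outcome), data)
  x <- rlang::eval_tidy(rlang::enquo(gc), data)
  keep <- !is.na(y) & !is.na(x)
  sel <- select_gc_order_xy(y[keep], x[keep], orders, tol)
  structure(sel$order, loo_r = sel$loo_r_by_order)
}

select_gc_order_xy <- function(y, x, orders, tol) {
  n <- length(y)
  if (n < 20L) stop("need at least 20 observations for order selection",
                    call. = FALSE)
  if (max(orders) >= n - 1L) stop("insufficient data for requested orders",
                                  call. = FALSE)
  loo_r <- vapply(orders, function(N) {
    if (length(unique(x)) <= N) return(NA_real_)
    X <- cbind(1, stats::poly(x, N))
    qr_x <- qr(X)
    h <- rowSums(qr.Q(qr_x)^2)
    fit <- qr.fitted(qr_x, y)
    loo_pred <- y - (y - fit) / (1 - h)
    stats::cor(loo_pred, y)
  }, double(1))
  best <- max(loo_r, na.rm = TRUE)
  order <- orders[which(!is.na(loo_r) & best - loo_r < tol)[1L]]
  list(order = as.integer(order), loo_r_by_order = setNames(loo_r, orders))
}

#' Remove the GC trend from segment activity estimates
#'
#' Fits GC polynomial trends for the given outcomes (on reference segments
#' only when a `role` column is present, so designed-mutation effects do not
#' leak into the GC curve) and fills the residual columns
#' `expression_residual` / `stability_residual` = value - polynomial(gc)
#' for **all** segments. Residuals carry into all downstream analyses.
#'
#' @param activity Segment activity tibble (from [summarize_segments()])
#'   with a `gc_fraction` column, or joinable to `segments`.
#' @param segments Optional segment annotation supplying `gc_fraction` and
#'   `role` by `segment_id`.
#' @param outcomes Character vector of outcome columns to residualize.
#' @param order Polynomial order or `"auto"` (LOO selection).
#' @param tol Passed to order selection.
#' @return `activity` with residual columns filled; fitted `gc_fit` objects
#'   are attached as attribute `"gc_fits"` (a named list).
#' @export
residualize <- function(activity, segments = NULL,
                        outcomes = c("steady_state_expression", "stability"),
                        order = 5L, tol = 0.002) {
  if (!is.null(segments)) {
    add <- intersect(c("gc_fraction", "role"), names(segments))
    activity <- dplyr::left_join(
      dplyr::select(activity, -dplyr::any_of(setdiff(add, "segment_id"))),
      segments[c("segment_id", add)],
      by = "segment_id"
    )
  }
  if (!"gc_fraction" %in% names(activity)) {
    stop("no gc_fraction column; supply `segments` or add it", call. = FALSE)
  }
  fit_rows <- if ("role" %in% names(activity)) {
    activity$role == "reference"
  } else rep(TRUE, nrow(activity))
  fits <- list()
  for (oc in intersect(outcomes, names(activity))) {
    fit <- fit_gc_polynomial(
      activity[fit_rows, ], outcome = .data[[oc]], gc = .data$gc_fraction,
      order = order, tol = tol
    )
    fit$outcome <- oc
    fits[[oc]] <- fit
    resid_col <- switch(oc,
      steady_state_expression = "expression_residual",
      stability = "stability_residual",
      paste0(oc, "_residual")
    )
    activity[[resid_col]] <-
      activity[[oc]] - predict(fit, activity$gc_fraction)
  }
  attr(activity, "gc_fits") <- fits
  activity
}

#' @rdname gc_fit_tidiers
#' @export
tidy.gc_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients)
  )
}

#' Tidy and summarize GC trend fits
#'
#' `tidy()` returns the monomial coefficients; `glance()` returns a one-row
#' summary with the order, sample size, in-sample r-squared, and (when order
#' selection ran) the LOO correlation at the chosen order.
#'
#' @param x A `gc_fit` object.
#' @param ... Unused.
#' @name gc_fit_tidiers
#' @export
glance.gc_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    order = x$order,
    n = x$n,
    r_squared = suppressWarnings(summary(x$model)$r.squared),
    loo_r = if (!is.null(x$loo_r_by_order)) {
      unname(x$loo_r_by_order[as.character(x$order)])
    } else NA_real_
  )
}
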