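#' Overlapping k-mer count matrix
#'
#' Breaks each sequence into its overlapping k-mers (a 160-nt segment
#' yields 156 5-mers) and counts occurrences of every possible k-mer.
#'
#' @param sequences Character vector of sequences, optionally named (names
#'   become row names).
#' @param k K-mer width.
#' @return An integer matrix with one row per sequence and `4^k` columns
#'   named by k-mer; row sums equal `nchar(sequence) - k + 1`.
#' @examples
#' rowSums(kmer_matrix(strrep("ACGU", 40)))
#' @export
kmer_matrix <- function(sequences, k = 5L) {
  k <- as.integer(k)
  sequences <- normalize_rna(sequences)
  if (any(nchar(sequences) < k)) {
    stop("all sequences must be at least k nt long", call. = FALSE)
  }
  kmers <- do.call(paste0, rev(expand.grid(
    rep(list(RNA_ALPHABET), k), stringsAsFactors = FALSE
  )))
  code <- setNames(0:3, RNA_ALPHABET)
  out <- matrix(0L, nrow = length(sequences), ncol = 4L^k,
                dimnames = list(names(sequences), kmers))
  pow <- 4L^((k - 1L):0L)
  for (i in seq_along(sequences)) {
    v <- code[strsplit(sequences[i], "")[[1]]]
    n <- length(v)
    idx <- rep(0L, n - k + 1L)
    for (j in seq_len(k)) idx <- idx + v[j:(n - k + j)] * pow[j]
    tab <- tabulate(idx + 1L, nbins = 4L^k)
    out[i, ] <- tab
  }
  out
}

#' Derive per-segment ARE features used by the categorical predictors
#'
#' Adds the representative-ARE fields (longest ARE, leftmost on ties) and
#' the cluster label to a segment table.
#'
#' @param data Tibble with a `sequence` column.
#' @return `data` with columns `cluster`, `are_length`,
#'   `are_start_registration`, `are_effective_length`,
#'   `are_naive_pentamers`, `has_are`, `total_effective_length` appended.
#' @export
segment_features <- function(data) {
  la <- longest_are(setNames(data$sequence, data$segment_id))
  data$cluster <- assign_cluster(data$sequence)
  data$are_length <- la$length
  data$are_start_registration <- la$start_registration
  data$are_effective_length <- la$effective_length
  data$are_naive_pentamers <- la$naive_pentamer_count
  data$has_are <- !is.na(la$length)
  data$total_effective_length <- total_effective_length(data$sequence)
  data
}

PREDICTOR_METHODS <- c(
  "ared_plus", "naive_pentamers", "effective_length", "score", "lasso_kmer"
)

predictor_category <- function(data, method) {
  switch(method,
    ared_plus = as.character(data$cluster),
    naive_pentamers = as.character(data$are_naive_pentamers),
    effective_length = as.character(data$are_effective_length),
    stop("method has no categorical representation", call. = FALSE)
  )
}

#' Leave-one-chromosome-out benchmarking of ARE activity predictors
#'
#' Splits segments by chromosome; for each chromosome, models are fitted on
#' the remaining chromosomes and the held-out segments are predicted, so
#' every test segment is predicted exactly once and overlapping genomic
#' windows never span a train/test split. Out-of-fold predictions are pooled
#' and the Pearson correlation with the measured values is reported.
#'
#' Methods: `"ared_plus"` (cluster label), `"naive_pentamers"` (effective
#' length in pentamer units), and `"effective_length"` (nt) are categorical
#' predictors whose training-set category means are used as test-set
#' predictions (an unseen category falls back to the global training mean);
#' `"score"` regresses the outcome linearly on a user-supplied continuous
#' per-segment score (e.g. an external ARE-scoring algorithm);
#' `"lasso_kmer"` fits an L1-penalized regression on overlapping k-mer
#' counts of *all* training segments (not only ARE-bearing ones).
#'
#' Evaluation is restricted to ARE-bearing segments (any periodic-AUUUA
#' match of length >= 6, or exact AUUUA). When `pairs` is supplied the
#' outcome is a designed-mutation delta: categorical methods train on
#' training-fold deltas grouped by the *reference* segment's category, while
#' the lasso trains on the raw outcome of all training segments and predicts
#' a delta as predicted(mutant) - predicted(reference).
#'
#' @param data Segment tibble with `segment_id`, `chromosome`, `sequence`,
#'   and the outcome column ([segment_features()] columns are computed if
#'   absent).
#' @param outcome Name (string) of the outcome column in `data`; for pair
#'   outcomes, the raw outcome used for lasso training.
#' @param method One of `r paste0('"', PREDICTOR_METHODS, '"', collapse = ", ")`.
#' @param pairs Optional pair tibble (`mutant_id`, `reference_id`, and the
#'   `pair_outcome` column) for mutation-effect prediction.
#' @param pair_outcome Name of the delta column in `pairs`
#'   (e.g. `"delta_stability"`).
#' @param score_col Name of the score column for `method = "score"`.
#' @param k K-mer width for the lasso.
#' @param seed Integer seed (controls lasso CV fold assignment).
#' @param lambda `"lambda.1se"` (default) or `"lambda.min"` penalty choice.
#' @return An object of class `loco_report`: `method`, `outcome`,
#'   `predictions` (tibble of ids, chromosome, observed, predicted),
#'   pooled Pearson `r`, and `n`. Supports `tidy()`, `glance()`,
#'   `autoplot()`.
#' @export
loco_cv <- function(data, outcome, method = PREDICTOR_METHODS, pairs = NULL,
                    pair_outcome = NULL, score_col = NULL, k = 5L,
                    seed = 1L, lambda = "lambda.1se") {
  method <- match.arg(method)
  if (!"has_are" %in% names(data)) data <- segment_features(data)
  if (length(unique(data$chromosome)) < 2L) {
    stop("need at least 2 chromosomes for leave-one-chromosome-out",
         call. = FALSE)
  }
  if (is.null(pairs)) {
    preds <- loco_segments(data, outcome, method, score_col, k, seed, lambda)
  } else {
    preds <- loco_pairs(data, outcome, method, pairs, pair_outcome,
                        score_col, k, seed, lambda)
  }
  keep <- !is.na(preds$observed) & !is.na(preds$predicted)
  structure(
    list(
      method = method,
      outcome = if (is.null(pairs)) outcome else pair_outcome,
      predictions = preds,
      r = stats::cor(preds$observed[keep], preds$predicted[keep]),
      n = sum(keep),
      pooled = TRUE
    ),
    class = "loco_report"
  )
}

loco_segments <- function(data, outcome, method, score_col, k, seed, lambda) {
  y_all <- data[[outcome]]
  test_mask <- data$has_are & !is.na(y_all)
  xk <- if (method == "lasso_kmer") {
    kmer_matrix(setNames(data$sequence, data$segment_id), k = k)
  }
  out <- list()
  for (chrom in unique(data$chromosome)) {
    test <- which(data$chromosome == chrom & test_mask)
    if (length(test) == 0L) next
    train <- which(data$chromosome != chrom & !is.na(y_all))
    pred <- switch(method,
      score = {
        tr <- data[train, ]
        fit <- stats::lm(tr[[outcome]] ~ tr[[score_col]])
        stats::coef(fit)[1] + stats::coef(fit)[2] * data[[score_col]][test]
      },
      lasso_kmer = {
        model <- fit_lasso(xk[train, , drop = FALSE], y_all[train],
                           seed = seed, lambda = lambda)
        as.numeric(predict(model, xk[test, , drop = FALSE]))
      },
      { # categorical methods train on ARE-bearing segments only
        tr <- which(data$chromosome != chrom & test_mask)
        category_predict(
          predictor_category(data[tr, ], method), y_all[tr],
          predictor_category(data[test, ], method)
        )
      }
    )
    out[[chrom]] <- tibble::tibble(
      segment_id = data$segment_id[test],
      chromosome = chrom,
      observed = y_all[test],
      predicted = pred
    )
  }
  dplyr::bind_rows(out)
}

loco_pairs <- function(data, outcome, method, pairs, pair_outcome,
                       score_col, k, seed, lambda) {
  stopifnot(!is.null(pair_outcome))
  ref <- data[match(pairs$reference_id, data$segment_id), ]
  mut_seq <- data$sequence[match(pairs$mutant_id, data$segment_id)]
  pairs$chromosome <- pairs[["chromosome"]] %||% ref$chromosome
  if (all(is.na(pairs$chromosome))) pairs$chromosome <- ref$chromosome
  delta <- pairs[[pair_outcome]]
  xk <- if (method == "lasso_kmer") {
    kmer_matrix(setNames(data$sequence, data$segment_id), k = k)
  }
  out <- list()
  for (chrom in unique(pairs$chromosome)) {
    test <- which(pairs$chromosome == chrom & !is.na(delta))
    if (length(test) == 0L) next
    train <- which(pairs$chromosome != chrom & !is.na(delta))
    pred <- switch(method,
      score = {
        fit <- stats::lm(delta[train] ~ ref[[score_col]][train])
        stats::coef(fit)[1] + stats::coef(fit)[2] * ref[[score_col]][test]
      },
      lasso_kmer = {
        seg_train <- which(data$chromosome != chrom & !is.na(data[[outcome]]))
        model <- fit_lasso(xk[seg_train, , drop = FALSE],
                           data[[outcome]][seg_train],
                           seed = seed, lambda = lambda)
        xm <- kmer_matrix(mut_seq[test], k = k)
        xr <- xk[match(pairs$reference_id[test], rownames(xk)), , drop = FALSE]
        as.numeric(predict(model, xm)) - as.numeric(predict(model, xr))
      },
      category_predict(
        predictor_category(ref[train, ], method), delta[train],
        predictor_category(ref[test, ], method)
      )
    )
    out[[chrom]] <- tibble::tibble(
      mutant_id = pairs$mutant_id[test],
      reference_id = pairs$reference_id[test],
      chromosome = chrom,
      observed = delta[test],
      predicted = pred
    )
  }
  dplyr::bind_rows(out)
}

# Training-category means as predictions; unseen categories fall back to the
# global training mean.
category_predict <- function(train_cat, train_y, test_cat) {
  means <- tapply(train_y, train_cat, mean)
  pred <- means[test_cat]
  pred[is.na(pred)] <- mean(train_y)
  unname(pred)
}

#' Fit a lasso k-mer regression model
#'
#' Solves y = Xb + c with an L1 penalty on the k-mer count matrix X. The
#' penalty is chosen by inner cross-validation on the training data using
#' the one-standard-error rule (deterministic given `seed`). A constant
#' outcome yields an all-zero coefficient vector.
#'
#' @param x K-mer count matrix ([kmer_matrix()]).
#' @param y Outcome vector.
#' @param seed Integer seed for fold assignment.
#' @param nfolds Inner CV folds.
#' @param lambda `"lambda.1se"` or `"lambda.min"`.
#' @param min_rows Minimum training rows required.
#' @return An object of class `kmer_model`: `intercept`, `coefficients`
#'   (named over all k-mers), `lambda`, `k`. Supports `predict()` and
#'   `tidy()`.
#' @export
fit_lasso <- function(x, y, seed = 1L, nfolds = 5L, lambda = "lambda.1se",
                      min_rows = 50L) {
  lambda <- match.arg(lambda, c("lambda.1se", "lambda.min"))
  if (nrow(x) < min_rows) {
    stop(sprintf("need at least %d training rows", min_rows), call. = FALSE)
  }
  k <- as.integer(round(log(ncol(x), 4)))
  if (stats::sd(y) == 0) {
    return(structure(
      list(intercept = y[1L],
           coefficients = setNames(numeric(ncol(x)), colnames(x)),
           lambda = Inf, k = k),
      class = "kmer_model"
    ))
  }
  cv <- withr::with_seed(as.integer(seed), {
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid)
  })
  co <- as.numeric(stats::coef(cv, s = lambda))
  structure(
    list(intercept = co[1L],
         coefficients = setNames(co[-1L], colnames(x)),
         lambda = unname(cv[[lambda]]), k = k),
    class = "kmer_model"
  )
}

#' @export
predict.kmer_model <- function(object, x, ...) {
  drop(x %*% object$coefficients) + object$intercept
}

#' @export
print.kmer_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<kmer_model> k = %d, %d nonzero of %d k-mer effects, lambda = %.4g\n",
              x$k, nz, length(x$coefficients), x$lambda))
  invisible(x)
}

#' @export
tidy.kmer_model <- function(x, ...) {
  co <- x$coefficients[x$coefficients != 0]
  tibble::tibble(kmer = names(co), estimate = unname(co)) |>
    dplyr::arrange(.data$estimate)
}

#' @export
print.loco_report <- function(x, ...) {
  cat(sprintf("<loco_report> %s on %s: pooled r = %.3f over %d held-out %s\n",
              x$method, x$outcome, x$r, x$n,
              if ("mutant_id" %in% names(x$predictions)) "pairs" else "segments"))
  invisible(x)
}

#' @rdname loco_tidiers
#' @export
tidy.loco_report <- function(x, ...) x$predictions

#' Tidy leave-one-chromosome-out reports
#'
#' `tidy()` returns the pooled out-of-fold predictions; `glance()` the
#' one-row summary (method, outcome, pooled Pearson r, n).
#'
#' @param x A `loco_report`.
#' @param ... Unused.
#' @name loco_tidiers
#' @export
glance.loco_report <- function(x, ...) {
  tibble::tibble(method = x$method, outcome = x$outcome, r = x$r, n = x$n,
                 pooled = x$pooled)
}

#' Compare two prediction methods by their squared out-of-fold residuals
#'
#' Runs a two-sided Mann-Whitney U test on the squared out-of-chromosome
#' residuals of two reports over their common test set; smaller residuals
#' mean better predictions.
#'
#' @param report_a,report_b `loco_report` objects over the same test
#'   segments (or pairs).
#' @return A one-row tibble: `u`, `p_value`, `better` (method name with the
#'   smaller mean squared residual, `"tie"` if equal), `mse_a`, `mse_b`, `n`.
#' @export
compare_methods <- function(report_a, report_b) {
  key <- intersect(
    c("segment_id", "mutant_id"), names(report_a$predictions)
  )[1L]
  a <- report_a$predictions
  b <- report_b$predictions
  common <- intersect(a[[key]], b[[key]])
  a <- a[match(common, a[[key]]), ]
  b <- b[match(common, b[[key]]), ]
  ra <- (a$observed - a$predicted)^2
  rb <- (b$observed - b$predicted)^2
  keep <- !is.na(ra) & !is.na(rb)
  ra <- ra[keep]; rb <- rb[keep]
  if (length(ra) < 2L) stop("need at least 2 residuals", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(ra, rb, alternative = "two.sided"))
  mse_a <- mean(ra); mse_b <- mean(rb)
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = wt$p.value,
    better = if (isTRUE(all.equal(mse_a, mse_b))) "tie" else if (mse_a < mse_b) report_a$method else report_b$method,
    mse_a = mse_a,
    mse_b = mse_b,
    n = length(ra)
  )
}
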