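# Small deterministic segment table for the categorical predictors: outcome
# depends linearly on effective length with tiny noise.
make_loco_data <- function(n = 240, n_chrom = 8, noise = 0.01, seed = 51) {
  withr::with_seed(seed, {
    eff <- sample(5:24, n, TRUE)
    g <- ifelse(eff == 5L, 0L, pmin(eff - 6L, sample(0:3, n, TRUE)))
    L <- eff - g
    seqs <- vapply(seq_len(n), function(i) {
      left <- paste(sample(c("G", "C"), 40, TRUE), collapse = "")
      right <- paste(sample(c("G", "C"), 40, TRUE), collapse = "")
      paste0(left, "G", oracle_pattern(g[i], L[i]), "G", right)
    }, character(1))
    tibble::tibble(
      segment_id = sprintf("s%04d", seq_len(n)),
      chromosome = paste0("chr", (seq_len(n) - 1L) %% n_chrom + 1L),
      sequence = seqs,
      stability = 0.6 - 0.015 * eff + rnorm(n, 0, noise)
    )
  })
}

test_that("k-mer matrix counts overlapping words against a dictionary oracle", {
  x <- kmer_matrix(strrep("ACGU", 40), k = 5)
  expect_equal(unname(rowSums(x)), 156)
  x <- kmer_matrix("AAAAAA", k = 5)
  expect_equal(unname(x[1, "AAAAA"]), 2L)
  expect_equal(sum(x), 2L)
  seqs <- random_rna(30, 25, seed = 52)
  m <- kmer_matrix(seqs, k = 3)
  for (i in c(1, 10, 30)) {
    want <- oracle_kmer_counts(seqs[i], 3)
    expect_equal(m[i, names(want)], unclass(want)[seq_along(want)],
                 ignore_attr = TRUE)
    expect_equal(sum(m[i, ]), 25 - 3 + 1)
  }
  expect_error(kmer_matrix("ACG", k = 5), "at least k")
})

test_that("categorical LOCO predicts held-out segments by training means", {
  d <- make_loco_data(noise = 0)
  rep_el <- loco_cv(d, "stability", method = "effective_length")
  # zero noise and a purely categorical outcome: pooled r = 1
  expect_equal(rep_el$r, 1, tolerance = 1e-9)
  # every ARE-bearing segment is predicted exactly once
  expect_equal(sort(rep_el$predictions$segment_id), sort(d$segment_id))
  # held-out predictions equal the training category mean, not the global one
  feat <- segment_features(d)
  chrom1 <- feat$chromosome == "chr1"
  train_means <- tapply(feat$stability[!chrom1],
                        feat$are_effective_length[!chrom1], mean)
  p1 <- rep_el$predictions[rep_el$predictions$chromosome == "chr1", ]
  cats <- as.character(feat$are_effective_length[match(p1$segment_id,
                                                       feat$segment_id)])
  expect_equal(p1$predicted, unname(train_means[cats]))
  expect_error(loco_cv(dplyr::mutate(d, chromosome = "chr1"), "stability",
                       method = "effective_length"),
               "at least 2 chromosomes")
})

test_that("on the training set a categorical predictor reproduces group means", {
  d <- segment_features(make_loco_data(n = 120, seed = 53))
  d <- d[d$has_are, ]
  cat <- as.character(d$are_effective_length)
  pred <- utrmpra:::category_predict(cat, d$stability, cat)
  expect_equal(pred, unname(tapply(d$stability, cat, mean)[cat]))
  # unseen categories fall back to the global training mean
  pred2 <- utrmpra:::category_predict(cat, d$stability, c("999", cat[1]))
  expect_equal(pred2[1], mean(d$stability))
})

test_that("the lasso recovers a planted k-mer effect and shrinks null data", {
  withr::with_seed(54, {
    seqs <- random_rna(300, 60)
    x <- kmer_matrix(seqs, k = 5)
    y_signal <- -0.02 * x[, "AUUUA"] + rnorm(300, 0, 0.004)
  })
  fit <- fit_lasso(x, y_signal, seed = 1)
  expect_lt(fit$coefficients[["AUUUA"]], 0)
  expect_lt(abs(fit$coefficients[["AUUUA"]] - (-0.02)), 0.01)
  # predictions track the planted outcome
  expect_gt(cor(predict(fit, x), y_signal), 0.8)
  # pure-noise outcome at the 1-SE penalty: (essentially) everything shrinks
  withr::with_seed(55, y_null <- rnorm(300, 0, 1))
  fit0 <- fit_lasso(x, y_null, seed = 1)
  expect_lt(sum(fit0$coefficients != 0), 10)
  # constant outcome: all-zero coefficients by contract
  fitc <- fit_lasso(x, rep(0.4, 300), seed = 1)
  expect_true(all(fitc$coefficients == 0))
  expect_equal(unname(predict(fitc, x[1:2, ])), c(0.4, 0.4))
  expect_error(fit_lasso(x[1:10, ], y_signal[1:10]), "at least 50")
  # determinism given the seed
  fit2 <- fit_lasso(x, y_signal, seed = 1)
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("k-mer predictions differ only through k-mers at mutated positions", {
  s <- paste0(strrep("GC", 30), "GAUUUAUUUAG", strrep("CG", 30))
  mut <- mutate_are(s)
  xr <- kmer_matrix(s, k = 5)
  xm <- kmer_matrix(mut, k = 5)
  changed <- which(xm[1, ] != xr[1, ])
  # only k-mers overlapping the mutated run can change counts
  m <- scan_ares(s)
  window <- substr(s, m$start - 3, m$start + m$length + 4)
  for (kmer in colnames(xr)[changed]) {
    expect_true(grepl(kmer, window, fixed = TRUE) ||
                  grepl(kmer, substr(mut, m$start - 3, m$start + m$length + 4),
                        fixed = TRUE))
  }
  # hence any kmer_model prediction difference is a function of those k-mers
  co <- setNames(numeric(ncol(xr)), colnames(xr))
  co[colnames(xr)[changed]] <- 0.1
  model <- structure(list(intercept = 0, coefficients = co, lambda = 1, k = 5),
                     class = "kmer_model")
  expect_equal(predict(model, xm) - predict(model, xr),
               sum(0.1 * (xm[1, changed] - xr[1, changed])),
               ignore_attr = TRUE)
})

test_that("pair-outcome LOCO trains on reference categories and lasso deltas", {
  d <- make_loco_data(n = 160, n_chrom = 4, noise = 0, seed = 56)
  feat <- segment_features(d)
  # build designed mutants and a delta that depends on the reference category
  muts <- d
  muts$segment_id <- paste0(d$segment_id, "_m")
  muts$sequence <- vapply(d$sequence, mutate_are, character(1))
  all_seg <- dplyr::bind_rows(d, muts)
  pairs <- tibble::tibble(
    mutant_id = muts$segment_id,
    reference_id = d$segment_id,
    delta_stability = 0.01 * feat$are_effective_length
  )
  rep_pair <- loco_cv(all_seg, outcome = "stability", pair_outcome = "delta_stability",
                      method = "effective_length", pairs = pairs)
  expect_equal(rep_pair$r, 1, tolerance = 1e-9)
  expect_equal(nrow(rep_pair$predictions), nrow(pairs))
})

test_that("method comparison on squared residuals is symmetric and calibrated", {
  mk_report <- function(resid, method) {
    structure(list(
      method = method, outcome = "stability",
      predictions = tibble::tibble(
        segment_id = sprintf("s%03d", seq_along(resid)),
        chromosome = "chr1", observed = resid, predicted = 0
      ),
      r = NA_real_, n = length(resid), pooled = TRUE
    ), class = "loco_report")
  }
  withr::with_seed(57, {
    base <- rnorm(500, 0, 1)
    a <- mk_report(base, "a")
    b <- mk_report(rnorm(500, 0, 1) * sqrt(2), "b")
  })
  # identical predictions: p = 1
  cmp_same <- compare_methods(a, a)
  expect_equal(cmp_same$p_value, 1)
  expect_equal(cmp_same$better, "tie")
  # swapping arguments flips the direction but keeps the p-value
  cmp_ab <- compare_methods(a, b)
  cmp_ba <- compare_methods(b, a)
  expect_equal(cmp_ab$p_value, cmp_ba$p_value)
  expect_equal(cmp_ab$better, "a")
  expect_equal(cmp_ba$better, "a")
  # a method with 2x lower residual variance is detected at n = 500
  withr::with_seed(58, {
    hits <- replicate(30, {
      x <- mk_report(rnorm(500, 0, 1), "a")
      y <- mk_report(rnorm(500, 0, sqrt(2)), "b")
      compare_methods(x, y)$p_value < 0.05
    })
  })
  expect_gte(mean(hits), 0.95)
  expect_error(compare_methods(mk_report(1, "a"), mk_report(1, "b")),
               "at least 2")
})

test_that("loco reports expose tidy predictions and a one-row summary", {
  d <- make_loco_data(n = 120, seed = 59)
  rep_np <- loco_cv(d, "stability", method = "naive_pentamers")
  td <- tidy(rep_np)
  expect_true(all(c("segment_id", "observed", "predicted") %in% names(td)))
  gl <- glance(rep_np)
  expect_equal(gl$method, "naive_pentamers")
  expect_equal(gl$n, nrow(td))
  expect_gt(gl$r, 0.5)
})
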