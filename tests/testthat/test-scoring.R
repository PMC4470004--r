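test_that("the sensitivity score is log10(P) shifted by K", {
  expect_equal(sensitivity_score(1), 5.2)
  expect_equal(sensitivity_score(10), 6.2)
  expect_equal(sensitivity_score(0.1), 4.2)
  expect_equal(sensitivity_score(100, K = 0), 2)
  expect_error(sensitivity_score(0), "positive")
  expect_error(sensitivity_score(-2), "positive")
})

test_that("responder classification matches the fold-change rule", {
  expect_equal(as.character(classify_responder(0.4)), "responder")
  expect_equal(as.character(classify_responder(1.7)), "non-responder")
  expect_equal(as.character(classify_responder(1.0)), "non-responder")
  expect_error(classify_responder(0), "positive")
  ## consistency: responder exactly when the score is below K
  P <- c(0.2, 0.9, 1, 1.3)
  expect_equal(classify_responder(P) == "responder",
               sensitivity_score(P) < 5.2)
})

mk_records <- function(treatment, x, y) {
  data.frame(sample_id = sprintf("c%02d", seq_along(x)),
             treatment = treatment, model_score = x,
             experimental_score = y, stringsAsFactors = FALSE)
}

test_that("per-treatment Pearson matches closed-form cases", {
  x <- 1:7
  rec <- rbind(mk_records("d1", x, 2 * x + 1),
               mk_records("d2", x, -x))
  out <- pearson_by_treatment(rec)
  expect_equal(out$r[out$treatment == "d1"], 1)
  expect_equal(out$r[out$treatment == "d2"], -1)
  ## p agrees with stats::cor.test
  rec2 <- mk_records("d3", c(1, 3, 2, 5, 4), c(2, 2.5, 2.2, 4.0, 3.1))
  out2 <- pearson_by_treatment(rec2)
  ref <- stats::cor.test(c(1, 3, 2, 5, 4), c(2, 2.5, 2.2, 4.0, 3.1))
  expect_equal(out2$r, unname(ref$estimate))
  expect_equal(out2$p, ref$p.value)
  expect_warning(pearson_by_treatment(mk_records("tiny", 1:2, 2:3)),
                 "fewer than 3")
  expect_warning(out3 <- pearson_by_treatment(mk_records("flat", 1:5,
                                                         rep(2, 5))),
                 "zero score variance")
  expect_true(is.na(out3$r))
})

test_that("pooled correlation removes per-treatment offsets", {
  x <- c(1, 2, 3, 4, 5)
  rec <- rbind(mk_records("a", x, x), mk_records("b", x + 10, x - 3))
  expect_equal(aggregate_correlation(rec), 1)
  ## balanced treatments with a common within-treatment r pool to that r
  withr::with_seed(11, {
    x1 <- stats::rnorm(40); y1 <- 0.6 * x1 + stats::rnorm(40, 0, 0.5)
    r_common <- stats::cor(x1, y1)
    rec2 <- rbind(mk_records("a", x1, y1),
                  mk_records("b", x1 + 5, y1 - 2))
    expect_equal(aggregate_correlation(rec2), r_common, tolerance = 1e-9)
  })
  ## arbitrary per-treatment offsets leave the pooled value unchanged
  base <- rbind(mk_records("a", stats::rnorm(10), stats::rnorm(10)),
                mk_records("b", stats::rnorm(10), stats::rnorm(10)))
  shifted <- base
  shifted$model_score <- base$model_score +
    ifelse(base$treatment == "a", 100, -40)
  shifted$experimental_score <- base$experimental_score +
    ifelse(base$treatment == "a", -7, 55)
  expect_equal(aggregate_correlation(shifted), aggregate_correlation(base),
               tolerance = 1e-9)
})

test_that("pure within-treatment noise pools to roughly zero", {
  withr::with_seed(42, {
    n <- 300
    rec <- rbind(mk_records("a", stats::rnorm(n), stats::rnorm(n)),
                 mk_records("b", stats::rnorm(n), stats::rnorm(n)))
    expect_lt(abs(aggregate_correlation(rec)), 2 / sqrt(2 * n))
  })
})

test_that("the correlation difference test behaves at its extremes", {
  withr::with_seed(7, {
    x <- stats::rnorm(12); y <- 0.8 * x + stats::rnorm(12, 0, 0.3)
    a <- rbind(mk_records("d1", x, y), mk_records("d2", x + 1, y - 1))
  })
  ## identical record sets: delta exactly 0 in every resample
  out <- correlation_difference_test(a, a, n_boot = 200, seed = 5)
  expect_equal(out$delta_r, 0)
  expect_gt(out$p, 0.99)
  ## determinism
  out2 <- correlation_difference_test(a, a, n_boot = 200, seed = 5)
  expect_identical(out, out2)
  ## swamping one score set with noise is detected
  b <- a
  withr::with_seed(8, {
    b$model_score <- stats::rnorm(nrow(b), 0, 20)
  })
  out3 <- correlation_difference_test(a, b, n_boot = 400, seed = 5)
  expect_lt(out3$p, 0.05)
  expect_warning(correlation_difference_test(a, a, n_boot = 50, seed = 1),
                 "n_boot")
})

test_that("AUC follows the rank formulation with midrank ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(1, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  ## invariant under strictly monotone transforms
  withr::with_seed(13, {
    sc <- stats::rnorm(50)
    lab <- stats::runif(50) < stats::plogis(2 * sc)
    a1 <- roc_auc(sc, lab)
    expect_equal(roc_auc(exp(sc), lab), a1)
    expect_equal(roc_auc(rank(sc), lab), a1)
  })
  ## agrees with an established implementation
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    sc <- stats::rnorm(60)
    lab <- stats::runif(60) < 0.4
    lab[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(sc, lab),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                                direction = "<"))))
  })
})

test_that("label-free scores give chance-level AUC", {
  withr::with_seed(31, {
    aucs <- vapply(1:20, function(i) {
      sc <- stats::rnorm(200)
      lab <- sample(rep(c(TRUE, FALSE), 100))
      roc_auc(sc, lab)
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.02)
  })
})
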