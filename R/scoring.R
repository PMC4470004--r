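#' Model-based sensitivity score
#'
#' `score = log10(P) + K`, where `P` is the hallmark fold change
#' (treatment over control) from the flux comparison and `K` (default
#' 5.2) shifts the score onto the scale of the experimental GI50
#' sensitivity score (the -log mol/L concentration yielding 50% growth
#' inhibition). Base-10 log keeps the score commensurate with that
#' -log10 molar scale.
#'
#' @param P Positive hallmark fold change(s).
#' @param K Additive constant (default 5.2).
#' @return Numeric score(s), strictly increasing in `P`.
#' @export
sensitivity_score <- function(P, K = 5.2) {
  if (any(!is.finite(P)) || any(P <= 0))
    stop("P must be positive and finite")
  log10(P) + K
}

#' Classify treatment response from the hallmark fold change
#'
#' Individuals whose proliferation hallmark under treatment falls below
#' its control value (`P < 1`) are responders; `P > 1` is a
#' non-responder. The boundary `P == 1` is classified non-responder so
#' the rule is deterministic, consistent with `sensitivity_score(P) < K`
#' characterizing responders.
#'
#' @param P Positive hallmark fold change(s).
#' @return Factor with levels `responder`, `non-responder`.
#' @export
classify_responder <- function(P) {
  if (any(!is.finite(P)) || any(P <= 0))
    stop("P must be positive and finite")
  factor(ifelse(P < 1, "responder", "non-responder"),
         levels = c("responder", "non-responder"))
}

check_records <- function(records) {
  need <- c("sample_id", "treatment", "model_score", "experimental_score")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data frame with columns: ",
         paste(need, collapse = ", "))
  records
}

#' Per-treatment Pearson correlation of model and experimental scores
#'
#' For each treatment with at least 3 paired records, the Pearson
#' correlation between model-based and experimentally based sensitivity
#' scores together with the two-sided t-based p-value.
#'
#' @param records Data frame with columns `sample_id`, `treatment`,
#'   `model_score`, `experimental_score`.
#' @return Data frame with columns `treatment`, `n`, `r`, `p`. Treatments
#'   with fewer than 3 pairs are skipped with a warning; zero-variance
#'   treatments yield `NA` and are flagged with a warning.
#' @export
pearson_by_treatment <- function(records) {
  records <- check_records(records)
  out <- lapply(split(records, records$treatment), function(d) {
    d <- d[is.finite(d$model_score) & is.finite(d$experimental_score), ]
    if (nrow(d) < 3L) {
      warning("treatment '", d$treatment[1] %||% "?",
              "' has fewer than 3 paired records; skipped")
      return(NULL)
    }
    if (stats::sd(d$model_score) == 0 || stats::sd(d$experimental_score) == 0) {
      warning("treatment '", d$treatment[1],
              "' has zero score variance; correlation undefined")
      return(data.frame(treatment = d$treatment[1], n = nrow(d),
                        r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(d$model_score, d$experimental_score,
                          method = "pearson")
    data.frame(treatment = d$treatment[1], n = nrow(d),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Pooled within-treatment correlation across all treatments
#'
#' Aggregates the correlation between model and experimental sensitivity
#' scores over all treatments by removing the per-treatment means from
#' both variables, pooling the centered pairs, and correlating — the
#' within-subject correlation of Bland & Altman, which measures the
#' association net of between-treatment score offsets.
#'
#' @param records Data frame as in [pearson_by_treatment()]; at least 2
#'   treatments with at least 3 pairs each.
#' @return Single correlation value (`NA` with a warning when the pooled
#'   variance is degenerate).
#' @export
aggregate_correlation <- function(records) {
  records <- check_records(records)
  records <- records[is.finite(records$model_score) &
                       is.finite(records$experimental_score), ]
  grp <- split(records, records$treatment)
  grp <- grp[vapply(grp, nrow, integer(1)) >= 3L]
  if (length(grp) < 2L)
    stop("need at least 2 treatments with at least 3 pairs each")
  cx <- unlist(lapply(grp, function(d) d$model_score - mean(d$model_score)))
  cy <- unlist(lapply(grp, function(d)
    d$experimental_score - mean(d$experimental_score)))
  if (stats::sd(cx) == 0 || stats::sd(cy) == 0) {
    warning("degenerate pooled variance; aggregate correlation undefined")
    return(NA_real_)
  }
  stats::cor(cx, cy)
}

#' Bootstrap test for a difference between two aggregate correlations
#'
#' Compares the pooled within-treatment correlations of two paired record
#' sets (the same samples and treatments scored two ways, e.g. with and
#' without miRNA expression input). Samples are resampled with
#' replacement; both aggregate correlations are recomputed on each
#' resample and the two-sided p-value for a zero difference is the
#' (continuity-corrected) fraction of resampled differences on either
#' side of zero. Deterministic for a fixed seed.
#'
#' @param records_A,records_B Data frames as in [pearson_by_treatment()],
#'   paired by `sample_id` and `treatment`.
#' @param n_boot Number of bootstrap resamples (default 2000; fewer than
#'   100 raises a warning).
#' @param seed Integer RNG seed.
#' @return List with `delta_r` (observed difference A - B), `p` and
#'   `n_boot`.
#' @export
correlation_difference_test <- function(records_A, records_B,
                                        n_boot = 2000L, seed = 1L) {
  records_A <- check_records(records_A)
  records_B <- check_records(records_B)
  if (n_boot < 100L) warning("n_boot < 100: p-value will be unstable")
  samples <- sort(unique(records_A$sample_id))
  if (!setequal(samples, unique(records_B$sample_id)))
    stop("record sets cover different samples")
  delta_obs <- aggregate_correlation(records_A) -
    aggregate_correlation(records_B)
  deltas <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample(samples, length(samples), replace = TRUE)
      ## resampled samples keep their multiplicity
      pick <- function(rec) {
        do.call(rbind, lapply(seq_along(take), function(i) {
          d <- rec[rec$sample_id == take[i], , drop = FALSE]
          d$sample_id <- paste0(d$sample_id, ".", i)
          d
        }))
      }
      dr <- tryCatch(
        aggregate_correlation(pick(records_A)) -
          aggregate_correlation(pick(records_B)),
        error = function(e) NA_real_, warning = function(w) NA_real_)
      dr
    }, numeric(1))
  })
  deltas <- deltas[is.finite(deltas)]
  n <- length(deltas)
  if (n == 0L) stop("all bootstrap resamples were degenerate")
  p_lo <- (sum(deltas <= 0) + 1) / (n + 1)
  p_hi <- (sum(deltas >= 0) + 1) / (n + 1)
  p <- min(1, 2 * min(p_lo, p_hi))
  list(delta_r = delta_obs, p = p, n_boot = n)
}

#' ROC area under the curve
#'
#' AUC via the rank (Mann-Whitney) formulation: the probability that a
#' randomly chosen positive scores higher than a randomly chosen
#' negative, with ties contributing 1/2.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param binary_labels Logical vector, or a two-level factor/vector
#'   whose second sorted level is taken as positive.
#' @return AUC in \code{[0, 1]}; errors when only one class is present.
#' @export
roc_auc <- function(scores, binary_labels) {
  if (is.logical(binary_labels)) {
    pos <- binary_labels
  } else {
    lv <- sort(unique(as.character(binary_labels)))
    if (length(lv) > 2L) stop("labels must be binary")
    pos <- as.character(binary_labels) == lv[length(lv)]
  }
  stopifnot(length(scores) == length(pos), all(is.finite(scores)))
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)              # midranks: ties contribute 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
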