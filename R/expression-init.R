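#' Read a two-column expression profile
#'
#' Reads a tab-separated file with columns `feature_id` (Ensembl gene ID
#' or miRNA ID) and `value` (non-negative expression) into a named
#' numeric vector.
#'
#' @param tsv_source Path to the TSV file (with header).
#' @param label Sample name attached as the `"label"` attribute.
#' @return Named numeric vector of class `expression_profile`.
#' @export
read_expression_profile <- function(tsv_source, label = basename(tsv_source)) {
  tab <- utils::read.delim(tsv_source, stringsAsFactors = FALSE)
  need <- c("feature_id", "value")
  if (!all(need %in% names(tab)))
    stop("expression TSV must have columns: ", paste(need, collapse = ", "))
  expression_profile(stats::setNames(as.numeric(tab$value), tab$feature_id),
                     label = label)
}

#' Construct an expression profile from a named vector
#'
#' @param values Named numeric vector: feature ID -> non-negative value.
#' @param label Sample name.
#' @return Named numeric vector of class `expression_profile`.
#' @export
expression_profile <- function(values, label = "sample") {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("expression profile requires unique feature IDs")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  structure(as.numeric(values), names = names(values),
            label = label, class = "expression_profile")
}

#' TMM library-size normalization
#'
#' Computes trimmed-mean-of-M-values scale factors for a raw count
#' matrix: per sample, a weighted trimmed mean of the gene-wise log2
#' ratios (M) against a reference sample, after trimming the 30% most
#' extreme M values and the 5% most extreme absolute intensities (A),
#' weighted by inverse asymptotic (binomial) variances. Factors are
#' rescaled to multiply to 1 in the geometric mean. The computation is
#' delegated to the reference implementation of the published method
#' (\code{edgeR::calcNormFactors}).
#'
#' @param count_matrix Numeric matrix of raw non-negative counts,
#'   features x samples, at least 2 samples (a single-sample matrix
#'   yields a factor of 1 with a warning).
#' @param reference_sample Optional column name or index of the reference
#'   sample; by default the sample whose upper quartile is closest to the
#'   mean upper quartile.
#' @return A list with `factors` (named per-sample scale factors),
#'   `normalized` (counts per million of effective library size: the
#'   matrix divided columnwise by `lib.size * factor`, times 1e6, so a
#'   sample's normalized values depend on no other library) and
#'   `lib_sizes`.
#' @export
tmm_normalize <- function(count_matrix, reference_sample = NULL) {
  m <- as.matrix(count_matrix)
  if (any(!is.finite(m)) || any(m < 0))
    stop("count matrix must be finite and non-negative")
  lib <- colSums(m)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[lib == 0], collapse = ", "))
  if (ncol(m) < 2L) {
    warning("single sample: TMM factor set to 1")
    f <- stats::setNames(rep(1, ncol(m)), colnames(m))
  } else {
    ref <- NULL
    if (!is.null(reference_sample)) {
      ref <- if (is.character(reference_sample))
        match(reference_sample, colnames(m)) else as.integer(reference_sample)
      if (is.na(ref) || ref < 1 || ref > ncol(m))
        stop("unknown reference sample: ", reference_sample)
    }
    f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref)
    names(f) <- colnames(m)
  }
  eff <- lib * f
  normalized <- sweep(m, 2L, eff, "/") * 1e6
  list(factors = f, normalized = normalized, lib_sizes = lib)
}

#' Initialize model concentrations from expression profiles
#'
#' Resets every species concentration to exactly zero, then sets
#' gene-kind species matched by Ensembl ID to their gene-expression value
#' and miRNA-gene species (ids of the form `miRgene:<mirna>`) matched by
#' miRNA ID to their miRNA-expression value. Matching is exact-string
#' after lowercasing (and stripping the `hsa-` prefix on miRNA IDs).
#' Expression values are used directly as token concentrations.
#' Initialization is a total reset: calling it twice with different
#' profiles leaves no residue of the first call. Unmatched profile
#' entries and unmatched model genes are counted and reported via
#' `message()`.
#'
#' @param model A [molecular_model()].
#' @param gene_profile Named numeric vector (or [expression_profile()]):
#'   Ensembl gene ID -> expression.
#' @param mirna_profile Named numeric vector: miRNA ID -> expression.
#' @return The initialized model.
#' @export
initialize_model <- function(model, gene_profile = NULL,
                             mirna_profile = NULL) {
  validate_model(model)
  gp <- if (is.null(gene_profile)) numeric() else
    stats::setNames(as.numeric(gene_profile), tolower(names(gene_profile)))
  mp <- if (is.null(mirna_profile)) numeric() else
    stats::setNames(as.numeric(mirna_profile),
                    normalize_mirna(names(mirna_profile)))
  if (any(gp < 0) || any(mp < 0)) stop("expression values must be >= 0")
  matched_g <- character(); matched_m <- character()
  unmatched_genes <- character()
  for (i in seq_along(model$species)) {
    s <- model$species[[i]]
    conc <- 0
    if (s$kind == "gene") {
      if (startsWith(s$id, "miRgene:")) {
        key <- normalize_mirna(sub("^miRgene:", "", s$id))
        v <- mp[key]
        if (!is.na(v)) { conc <- v; matched_m <- c(matched_m, key) }
        else unmatched_genes <- c(unmatched_genes, s$id)
      } else {
        v <- gp[tolower(s$id)]
        if (!is.na(v)) { conc <- v; matched_g <- c(matched_g, tolower(s$id)) }
        else unmatched_genes <- c(unmatched_genes, s$id)
      }
    }
    model$species[[i]]$concentration <- unname(conc)
  }
  orphans <- sum(!names(gp) %in% matched_g) + sum(!names(mp) %in% matched_m)
  if (orphans > 0)
    message(orphans, " profile feature(s) absent from the model")
  if (length(unmatched_genes))
    message(length(unmatched_genes),
            " model gene(s) absent from the profiles stay at 0")
  model
}
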