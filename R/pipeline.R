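#' Assemble a pipeline run configuration
#'
#' @param model_xml Path to the model XML.
#' @param gene_tsv Path to the gene-expression TSV (`feature_id`,
#'   `value`).
#' @param drug Drug name (built-in) or a [drug_spec()].
#' @param out_dir Output directory (created if missing).
#' @param mirt_tsv,tfmir_tsv Optional regulation tables; when given, the
#'   model is extended with miRNA regulation before initialization.
#' @param mirna_tsv Optional miRNA-expression TSV.
#' @param inhibitor_conc Administered inhibitor concentration (default 1).
#' @param sim Optional [sim_config()] overrides.
#' @param seed Integer seed recorded in the output provenance (the
#'   pipeline itself is deterministic; the seed matters when the inputs
#'   were generated from it).
#' @param sample_id Label used in the result tables.
#' @return A `run_config` list.
#' @export
run_config <- function(model_xml, gene_tsv, drug, out_dir,
                       mirt_tsv = NULL, tfmir_tsv = NULL, mirna_tsv = NULL,
                       inhibitor_conc = 1, sim = sim_config(),
                       seed = NA_integer_, sample_id = "sample") {
  for (p in c(model_xml, gene_tsv, mirt_tsv, tfmir_tsv, mirna_tsv)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(model_xml = model_xml, gene_tsv = gene_tsv, drug = drug,
                 out_dir = out_dir, mirt_tsv = mirt_tsv,
                 tfmir_tsv = tfmir_tsv, mirna_tsv = mirna_tsv,
                 inhibitor_conc = inhibitor_conc, sim = sim, seed = seed,
                 sample_id = sample_id),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full prediction pipeline
#'
#' Executes model loading, optional miRNA extension, expression
#' initialization, the flux comparison (control plus treatment) and
#' sensitivity scoring, writing `fca_results.tsv` (per-readout fold
#' changes), `scores.tsv` (sensitivity scores and responder calls) and
#' `provenance.json` (package version, seed, config echo, output
#' inventory) into the output directory. Any stage failure aborts with a
#' stage-named error.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `fca` (the [run_fca()] result),
#'   `scores` (data frame) and `files` (written paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  model <- stage("read_model", read_model(config$model_xml))
  if (!is.null(config$mirt_tsv)) {
    mirt <- stage("load_mirt", load_mirt(config$mirt_tsv))
    tfmir <- if (!is.null(config$tfmir_tsv))
      stage("load_tfmir", load_tfmir(config$tfmir_tsv)) else NULL
    model <- stage("extend_model", extend_model(model, mirt, tfmir))
  }
  gp <- stage("read_expression", read_expression_profile(config$gene_tsv))
  mp <- if (!is.null(config$mirna_tsv))
    stage("read_expression", read_expression_profile(config$mirna_tsv))
  else NULL
  model <- stage("initialize_model", initialize_model(model, gp, mp))
  fca <- stage("run_fca",
               run_fca(model, config$drug,
                       inhibitor_conc = config$inhibitor_conc,
                       config = config$sim))
  scores <- stage("score", {
    ok <- !is.na(fca$P)
    data.frame(sample_id = config$sample_id,
               treatment = fca$drug,
               readout = names(fca$P),
               P = unname(fca$P),
               model_score = ifelse(ok, sensitivity_score(fca$P[ok]),
                                    NA_real_),
               responder = ifelse(ok,
                                  as.character(classify_responder(
                                    pmax(fca$P, .Machine$double.xmin))),
                                  NA_character_),
               stringsAsFactors = FALSE)
  })
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  f_fca <- file.path(config$out_dir, "fca_results.tsv")
  f_scores <- file.path(config$out_dir, "scores.tsv")
  f_prov <- file.path(config$out_dir, "provenance.json")
  fca_tab <- data.frame(readout = names(fca$P), P = unname(fca$P),
                        flux_P = unname(fca$flux_P),
                        control_steady = fca$control$reached_steady,
                        treatment_steady = fca$treatment$reached_steady,
                        stringsAsFactors = FALSE)
  utils::write.table(fca_tab, f_fca, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scores, f_scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov <- list(
    package = "fluxnetmir",
    version = as.character(utils::packageVersion("fluxnetmir")),
    seed = config$seed,
    config = list(model_xml = config$model_xml, gene_tsv = config$gene_tsv,
                  mirna_tsv = config$mirna_tsv, mirt_tsv = config$mirt_tsv,
                  tfmir_tsv = config$tfmir_tsv,
                  drug = if (is.character(config$drug)) config$drug
                         else config$drug$name,
                  inhibitor_conc = config$inhibitor_conc,
                  sim = unclass(config$sim)),
    outputs = c("fca_results.tsv", "scores.tsv", "provenance.json")
  )
  jsonlite::write_json(prov, f_prov, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(fca = fca, scores = scores,
                 files = c(f_fca, f_scores, f_prov)))
}

#' Write synthetic fixtures to disk
#'
#' Emits a complete pipeline input set generated from one
#' [fixture_spec()]: `model.xml`, `miRT.tsv`, `TFmiR.tsv`, per-sample
#' expression profiles under `cohort/`, and `truth.tsv` with the planted
#' labels.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory.
#' @param n_responders,n_nonresponders Cohort group sizes.
#' @return Invisibly, the list of written paths.
#' @export
write_fixtures <- function(spec, out_dir, n_responders = 5L,
                           n_nonresponders = 5L) {
  dir.create(file.path(out_dir, "cohort"), showWarnings = FALSE,
             recursive = TRUE)
  toy <- gen_toy_model(spec)
  tables <- gen_mir_tables(spec)
  cohort <- gen_cohort(spec, n_responders, n_nonresponders)
  paths <- character()
  w <- function(x, f) {
    p <- file.path(out_dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  p_model <- file.path(out_dir, "model.xml")
  write_model(toy$model, p_model); paths <- c(paths, p_model)
  mirt_df <- do.call(rbind, lapply(names(tables$mirt), function(g)
    cbind(gene_id = g, tables$mirt[[g]])))
  if (is.null(mirt_df))
    mirt_df <- data.frame(gene_id = character(), mirna_id = character(),
                          pubmed = character())
  w(mirt_df, "miRT.tsv")
  tf_df <- do.call(rbind, lapply(names(tables$tfmir), function(m)
    cbind(mirna_id = m, tables$tfmir[[m]])))
  if (is.null(tf_df))
    tf_df <- data.frame(mirna_id = character(), tf_gene_id = character(),
                        regulation = character(), pubmed = character())
  w(tf_df, "TFmiR.tsv")
  truth <- data.frame(sample_id = vapply(cohort, `[[`, "", "sample_id"),
                      true_label = vapply(cohort, `[[`, "", "true_label"))
  w(truth, "truth.tsv")
  for (s in cohort) {
    w(data.frame(feature_id = names(s$gene_profile),
                 value = unname(s$gene_profile)),
      file.path("cohort", paste0(s$sample_id, "_genes.tsv")))
    w(data.frame(feature_id = names(s$mirna_profile),
                 value = unname(s$mirna_profile)),
      file.path("cohort", paste0(s$sample_id, "_mirnas.tsv")))
  }
  invisible(paths)
}

#' Simulate and score a whole synthetic cohort
#'
#' End-to-end label recovery on generated data: builds the toy model,
#' splices in the miRNA regulation tables, then for every cohort member
#' initializes the model with that individual's expression, runs the
#' flux comparison under the given drug and scores the response. The
#' discrimination of the planted responder labels is summarized as the
#' ROC AUC of the (negated) sensitivity score, so 1 means responders
#' were perfectly recovered and 0.5 is chance.
#'
#' @param spec A [fixture_spec()]; its `effect_size` and `noise_sd` set
#'   the planted separation.
#' @param n_responders,n_nonresponders Cohort group sizes.
#' @param drug Drug name or [drug_spec()] (default `"everolimus"`, which
#'   targets the fixture kinase).
#' @param inhibitor_conc Administered concentration in nM (default 220,
#'   i.e. 100x the everolimus dissociation constant).
#' @param config A [sim_config()].
#' @return A list with `results` (data frame: sample_id, true_label, P,
#'   model_score, responder, reached_steady) and `auc`.
#' @export
evaluate_cohort <- function(spec, n_responders, n_nonresponders,
                            drug = "everolimus", inhibitor_conc = 220,
                            config = sim_config()) {
  toy <- gen_toy_model(spec)
  tabs <- gen_mir_tables(spec)
  model <- extend_model(toy$model, tabs$mirt, tabs$tfmir)
  cohort <- gen_cohort(spec, n_responders, n_nonresponders)
  rows <- lapply(cohort, function(s) {
    m <- suppressMessages(
      initialize_model(model, s$gene_profile, s$mirna_profile))
    r <- run_fca(m, drug, inhibitor_conc = inhibitor_conc, config = config)
    P <- r$P[[1]]
    data.frame(sample_id = s$sample_id, true_label = s$true_label,
               P = P,
               model_score = if (is.na(P)) NA_real_
                             else sensitivity_score(P),
               responder = if (is.na(P)) NA_character_
                           else as.character(classify_responder(P)),
               reached_steady = r$control$reached_steady &&
                 r$treatment$reached_steady,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  auc <- roc_auc(-results$model_score, results$true_label == "responder")
  list(results = results, auc = auc)
}
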