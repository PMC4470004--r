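#' Create a drug specification
#'
#' A drug is a named set of targets, each with an experimentally measured
#' dissociation constant `iKd` in nM. During treatment, every model
#' reaction catalyzed by a target gains the inhibitor factor
#' `iKd / [I]` in its mass-action speed.
#'
#' @param name Drug name.
#' @param targets Data frame with columns `target` (protein or complex
#'   name) and `ikd_nm` (dissociation constant, nM, > 0).
#' @return An object of class `drug_spec`.
#' @export
drug_spec <- function(name, targets) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.data.frame(targets) ||
      !all(c("target", "ikd_nm") %in% names(targets)) ||
      nrow(targets) == 0L)
    stop("targets must be a non-empty data frame with columns target, ikd_nm")
  targets <- data.frame(target = as.character(targets$target),
                        ikd_nm = as.numeric(targets$ikd_nm),
                        stringsAsFactors = FALSE)
  if (any(!is.finite(targets$ikd_nm)) || any(targets$ikd_nm <= 0))
    stop("every target must carry ikd_nm > 0")
  structure(list(name = name, targets = targets), class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(x$name, "-> targets:\n")
  for (i in seq_len(nrow(x$targets)))
    cat(sprintf("  %-14s iKd = %g nM\n", x$targets$target[i],
                x$targets$ikd_nm[i]))
  invisible(x)
}

#' The built-in drug catalogue
#'
#' Twelve signaling agents with published dissociation constants: the ten
#' tyrosine-kinase inhibitors dasatinib, erlotinib, everolimus,
#' gefitinib, imatinib, lapatinib, nilotinib, sorafenib, sunitinib and
#' temsirolimus (multi-target entries kept verbatim, including the
#' combined dasatinib target label "EPHA5/8" and temsirolimus's indirect
#' VEGFR entry), plus sirolimus (mTor complex II, 0.65 nM) and LY294002
#' (PI3K, 210 nM).
#'
#' @return Named list of [drug_spec()] objects.
#' @export
builtin_drugs <- function() {
  d <- function(name, ...) {
    tt <- matrix(c(...), ncol = 2, byrow = TRUE)
    drug_spec(name, data.frame(target = tt[, 1],
                               ikd_nm = as.numeric(tt[, 2]),
                               stringsAsFactors = FALSE))
  }
  drugs <- list(
    d("dasatinib", "ABL1", 0.53, "EPHA3", 0.09, "EPHA5/8", 0.24,
      "PDGFRA", 0.47, "LYN", 0.57, "KIT", 0.62, "SRC", 0.21),
    d("erlotinib", "EGFR", 0.67, "ERBB4", 230, "LYN", 530, "SRC", 700),
    d("everolimus", "MTOR", 2.2),
    d("gefitinib", "EGFR", 1.0, "ERBB2", 3500, "ERBB4", 410, "LYN", 990),
    d("imatinib", "ABL1", 12.0, "ABL2", 10.0, "KIT", 14.0,
      "PDGFRA", 31.0, "PDGFRB", 14.0),
    d("lapatinib", "EGFR", 2.4, "ERBB2", 7.0, "ERBB4", 54.0),
    d("nilotinib", "KIT", 22, "PDGFRB", 22),
    d("sorafenib", "DDR1", 1.5, "DDR2", 6.6),
    d("sunitinib", "FLT3", 0.47, "KIT", 0.37, "PDGFRA", 0.79,
      "PDGFRB", 0.08),
    d("temsirolimus", "MTOR", 2.2, "VEGFR", 0.75),
    d("sirolimus", "mTor complex II", 0.65),
    d("LY294002", "PI3K", 210)
  )
  names(drugs) <- vapply(drugs, `[[`, character(1), "name")
  drugs
}

#' Load user drug specifications from TSV
#'
#' Reads a tab-separated file with columns `name`, `target`, `ikd_nm`
#' (one row per target) into drug specifications usable beside the
#' built-ins.
#'
#' @param tsv_source Path to the TSV file.
#' @return Named list of [drug_spec()] objects.
#' @export
load_drugs <- function(tsv_source) {
  tab <- utils::read.delim(tsv_source, stringsAsFactors = FALSE)
  need <- c("name", "target", "ikd_nm")
  if (!all(need %in% names(tab)))
    stop("drug TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$name), function(d)
    drug_spec(d$name[1], data.frame(target = d$target, ikd_nm = d$ikd_nm)))
  out[unique(tab$name)]
}

## Enzyme identity normalization: drugs are specified by gene-symbol
## targets, model species may carry phospho-prefixed or differently cased
## names. Matching is case-insensitive with a leading "P-" stripped.
normalize_target <- function(x) {
  x <- tolower(x)
  sub("^p-", "", x)
}

#' Apply a drug treatment to a model
#'
#' Annotates every reaction whose enzyme list contains a drug target with
#' an inhibitor entry (the drug name, the matched target's iKd, and the
#' administered concentration `[I]`). Target matching compares normalized
#' enzyme species names and ids (case-insensitive, phospho-prefix "P-"
#' stripped). Nothing else is changed — species, kinetic parameters, eKd
#' and the network topology are untouched, and the input model is not
#' modified (a treated copy is returned). A reaction catalyzed by two
#' matched targets gains both inhibitor factors.
#'
#' @param model A [molecular_model()].
#' @param drug A [drug_spec()] or the name of a built-in drug.
#' @param inhibitor_conc Administered inhibitor concentration (nM scale,
#'   same units as iKd; default 1).
#' @return The treated model. If no reaction matches any target a warning
#'   is raised and the model is returned unchanged (FCA then yields
#'   P = 1).
#' @export
apply_treatment <- function(model, drug, inhibitor_conc = 1) {
  validate_model(model)
  if (is.character(drug)) {
    cat_ <- builtin_drugs()
    if (!drug %in% names(cat_)) stop("unknown drug: ", drug)
    drug <- cat_[[drug]]
  }
  stopifnot(inherits(drug, "drug_spec"), inhibitor_conc >= 0)
  tnorm <- normalize_target(drug$targets$target)
  sp_norm_name <- normalize_target(
    vapply(model$species, function(s) s$name, character(1)))
  sp_norm_id <- normalize_target(names(model$species))
  n_hit <- 0L
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    if (!length(r$enzymes)) next
    eidx <- match(r$enzymes, names(model$species))
    enorm_name <- sp_norm_name[eidx]
    enorm_id <- sp_norm_id[eidx]
    hit <- which(tnorm %in% c(enorm_name, enorm_id))
    if (length(hit)) {
      add <- data.frame(ref = drug$name,
                        iKd = drug$targets$ikd_nm[hit],
                        conc = inhibitor_conc,
                        stringsAsFactors = FALSE)
      model$reactions[[i]]$inhibitors <-
        rbind(r$inhibitors, add)
      n_hit <- n_hit + 1L
    }
  }
  if (n_hit == 0L)
    warning("drug '", drug$name,
            "' matches no catalyzed reaction in the model; returned unchanged")
  model
}
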