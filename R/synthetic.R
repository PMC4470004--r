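#' Specification of a synthetic fixture family
#'
#' One seeded specification drives the toy-model generator, the
#' regulation-table generator and the cohort generator, so a full
#' pipeline fixture is reproducible from a single object.
#'
#' The generated model is a star of per-gene linear cascades
#' (gene -> mRNA -> protein, optionally -> phospho-protein) feeding one
#' `proliferation` pseudo-object hallmark. One designated gene's protein
#' is the drug-target kinase (named `MTOR` so the built-in mTOR
#' inhibitors resolve against it); the remaining genes split into a
#' kinase-dependent branch (their proteins are phosphorylated by the
#' kinase before activating the hallmark) and a kinase-independent branch
#' (their proteins activate the hallmark directly). Drug response of an
#' individual is then governed by how much of their hallmark flux routes
#' through the druggable branch.
#'
#' @param seed Integer seed; identical specs generate identical output.
#' @param n_genes Number of genes (>= 1; default 5).
#' @param n_mirnas Number of miRNAs in the regulation tables (default 2).
#' @param chain_depth 3 (gene, mRNA, protein) or 4 (adds the
#'   phospho-protein stage; default).
#' @param drug_target_gene Index of the kinase gene (default 1).
#' @param effect_size Multiplicative separation between responder and
#'   non-responder pathway activity in generated cohorts (default 1,
#'   i.e. no planted signal).
#' @param noise_sd Standard deviation of the log-normal expression noise
#'   on the log scale (default 0.25).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 5L, n_mirnas = 2L,
                         chain_depth = 4L, drug_target_gene = 1L,
                         effect_size = 1, noise_sd = 0.25) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (n_mirnas < 0L) stop("n_mirnas must be >= 0")
  if (!chain_depth %in% c(3L, 4L)) stop("chain_depth must be 3 or 4")
  if (drug_target_gene < 1L || drug_target_gene > n_genes)
    stop("drug_target_gene out of range")
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 chain_depth = as.integer(chain_depth),
                 drug_target_gene = as.integer(drug_target_gene),
                 effect_size = effect_size, noise_sd = noise_sd),
            class = "fixture_spec")
}

fixture_gene_ids <- function(spec) sprintf("ENSG%011d", seq_len(spec$n_genes))

fixture_roles <- function(spec) {
  gene_ids <- fixture_gene_ids(spec)
  target <- gene_ids[spec$drug_target_gene]
  others <- setdiff(gene_ids, target)
  if (length(others)) {
    dependent <- others[seq_len(ceiling(length(others) / 2))]
    independent <- setdiff(others, dependent)
  } else {
    dependent <- target   # single-gene model: autophosphorylation loop
    independent <- character()
  }
  list(gene_ids = gene_ids, target = target,
       dependent = dependent, independent = independent)
}

#' Generate a toy molecular model with known composition
#'
#' Deterministically builds the cascade model described in
#' [fixture_spec()] together with a generator-side census tally, so the
#' model's [census()] can be asserted against independent bookkeeping.
#' Default kinetics: production/transport reactions k = 0.01, protein
#' decay k = 0.05, mRNA and hallmark decay k = 0.1, hallmark activation
#' k = 0.002, kinase-catalyzed phosphorylation eKd = 10 — chosen so every
#' steady state is rate-limited: speeds stay well below the 0.75 firing
#' cap and every accumulating species equilibrates strictly below its
#' firing guards at token concentrations on the order of 1-100.
#'
#' @param spec A [fixture_spec()].
#' @return List with `model` (a [molecular_model()]), `tally` (expected
#'   per-kind species and per-rtype reaction counts), and `info` (gene
#'   ids and branch roles).
#' @export
gen_toy_model <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  roles <- fixture_roles(spec)
  sp <- list(); rx <- list()
  tally_sp <- stats::setNames(integer(length(SPECIES_KINDS)), SPECIES_KINDS)
  tally_rx <- stats::setNames(integer(length(REACTION_TYPES)), REACTION_TYPES)
  add_sp <- function(s) { sp[[length(sp) + 1L]] <<- s
    tally_sp[s$kind] <<- tally_sp[s$kind] + 1L }
  add_rx <- function(r) { rx[[length(rx) + 1L]] <<- r
    tally_rx[r$rtype] <<- tally_rx[r$rtype] + 1L }

  add_sp(species("proliferation", "pseudo-object", compartment = "cytoplasm"))
  add_rx(reaction("dec:proliferation", "decay", reactants = "proliferation",
                  k = 0.1))
  kin_prot <- paste0("prot:", roles$target)
  for (i in seq_along(roles$gene_ids)) {
    g <- roles$gene_ids[i]
    mrna <- paste0("mRNA:", g); prot <- paste0("prot:", g)
    is_target <- g == roles$target
    add_sp(species(g, "gene", name = sprintf("G%d", i),
                   compartment = "nucleus"))
    add_sp(species(mrna, "mRNA", compartment = "cytoplasm"))
    add_sp(species(prot, "protein",
                   name = if (is_target) "MTOR" else sprintf("P%d", i),
                   compartment = "cytoplasm"))
    add_rx(reaction(paste0("tc:", g), "transcription", enzymes = g,
                    products = mrna, k = 0.01))
    add_rx(reaction(paste0("dec:mRNA:", g), "decay", reactants = mrna,
                    k = 0.1))
    add_rx(reaction(paste0("tl:", g), "translation", enzymes = mrna,
                    products = prot, k = 0.01))
    add_rx(reaction(paste0("dec:prot:", g), "decay", reactants = prot,
                    k = 0.05))
    if (g %in% roles$dependent) {
      if (spec$chain_depth == 4L) {
        pprot <- paste0("pprot:", g)
        add_sp(species(pprot, "protein", name = sprintf("P-P%d", i),
                       compartment = "cytoplasm"))
        add_rx(reaction(paste0("ph:", g), "phosphorylation",
                        reactants = prot, products = pprot,
                        enzymes = kin_prot, k = 0.01, eKd = 10))
        add_rx(reaction(paste0("dec:pprot:", g), "decay",
                        reactants = pprot, k = 0.05))
        add_rx(reaction(paste0("act:", g), "activation", enzymes = pprot,
                        products = "proliferation", k = 0.002))
      } else {
        add_rx(reaction(paste0("act:", g), "activation",
                        enzymes = unique(c(prot, kin_prot)),
                        products = "proliferation", k = 0.002, eKd = 10))
      }
    } else if (g %in% roles$independent) {
      add_rx(reaction(paste0("act:", g), "activation", enzymes = prot,
                      products = "proliferation", k = 0.002))
    }
  }
  model <- molecular_model(sp, rx, readouts = "proliferation")
  list(model = model,
       tally = list(species = tally_sp, reactions = tally_rx,
                    n_species = sum(tally_sp), n_reactions = sum(tally_rx)),
       info = roles)
}

#' Generate companion miRNA regulation tables
#'
#' Builds a miRNA-target table and a TF-miRNA table whose identifiers all
#' resolve in the companion [gen_toy_model()] model. The first miRNA
#' (`mir-f1`) is planted on the first kinase-dependent gene, making it a
#' proliferation-repressing miRNA whose expression tunes the druggable
#' branch; remaining miRNAs are assigned random target genes, and a
#' random subset of those gains an activating or repressing transcription
#' factor (the planted miRNA stays TF-free so its cohort signal is
#' unconfounded). Deterministic for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @return List with `mirt` ([mirt_table()]) and `tfmir`
#'   ([tfmir_table()]).
#' @export
gen_mir_tables <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  roles <- fixture_roles(spec)
  if (spec$n_mirnas == 0L) {
    return(list(mirt = mirt_table(data.frame(gene_id = character(),
                                             mirna_id = character(),
                                             pubmed = character())),
                tfmir = tfmir_table(data.frame(mirna_id = character(),
                                               tf_gene_id = character(),
                                               regulation = character(),
                                               pubmed = character()))))
  }
  mirna_ids <- sprintf("mir-f%d", seq_len(spec$n_mirnas))
  withr::with_seed(spec$seed + 1L, {
    target_gene <- c(roles$dependent[1],
                     if (spec$n_mirnas > 1L)
                       sample(roles$gene_ids, spec$n_mirnas - 1L,
                              replace = TRUE))
    mirt_df <- data.frame(gene_id = target_gene, mirna_id = mirna_ids,
                          pubmed = sprintf("10%06d", seq_len(spec$n_mirnas)),
                          stringsAsFactors = FALSE)
    tf_rows <- NULL
    if (spec$n_mirnas > 1L) {
      with_tf <- mirna_ids[-1][sample.int(spec$n_mirnas - 1L) <=
                                 ceiling((spec$n_mirnas - 1L) / 2)]
      if (length(with_tf)) {
        tf_rows <- data.frame(
          mirna_id = with_tf,
          tf_gene_id = sample(roles$gene_ids, length(with_tf),
                              replace = TRUE),
          regulation = sample(c("activation", "repression"),
                              length(with_tf), replace = TRUE),
          pubmed = sprintf("20%06d", seq_along(with_tf)),
          stringsAsFactors = FALSE)
      }
    }
    if (is.null(tf_rows))
      tf_rows <- data.frame(mirna_id = character(),
                            tf_gene_id = character(),
                            regulation = character(),
                            pubmed = character())
    list(mirt = mirt_table(mirt_df), tfmir = tfmir_table(tf_rows))
  })
}

#' Generate a synthetic expression cohort with planted responder structure
#'
#' Draws per-sample gene and miRNA expression profiles with log-normal
#' noise. Responders get the drug-target pathway (the kinase gene and
#' every kinase-dependent gene) elevated by `effect_size` and the
#' proliferation-repressing miRNAs (those targeting kinase-dependent
#' genes) lowered by the same factor, so that a flux comparison under the
#' planted drug yields clearly reduced hallmark fold changes for
#' responders when the effect size is large. `effect_size = 1` plants no
#' signal (the null). Baseline medians are 20 expression units for genes
#' and 10 for miRNAs, a scale at which every bimolecular speed stays
#' below the engine's 0.75 firing cap throughout the simulation.
#'
#' @param spec A [fixture_spec()] (its `effect_size` and `noise_sd` are
#'   the planted conditions).
#' @param n_responders,n_nonresponders Group sizes.
#' @return List of samples; each is a list with `sample_id`,
#'   `gene_profile`, `mirna_profile` (named numeric vectors) and
#'   `true_label` (`"responder"` / `"non-responder"`).
#' @export
gen_cohort <- function(spec, n_responders, n_nonresponders) {
  stopifnot(inherits(spec, "fixture_spec"),
            n_responders >= 0, n_nonresponders >= 0)
  roles <- fixture_roles(spec)
  tables <- gen_mir_tables(spec)
  pathway <- unique(c(roles$target, roles$dependent))
  mirna_ids <- sprintf("mir-f%d", seq_len(spec$n_mirnas))
  repressing <- vapply(mirna_ids, function(m) {
    any(vapply(tables$mirt, function(d) m %in% d$mirna_id, logical(1))[
      names(tables$mirt) %in% roles$dependent])
  }, logical(1))
  labels <- c(rep("responder", n_responders),
              rep("non-responder", n_nonresponders))
  withr::with_seed(spec$seed + 2L, {
    lapply(seq_along(labels), function(i) {
      resp <- labels[i] == "responder"
      g <- 20 * exp(stats::rnorm(spec$n_genes, 0, spec$noise_sd))
      names(g) <- roles$gene_ids
      if (resp) g[pathway] <- g[pathway] * spec$effect_size
      m <- numeric(0)
      if (spec$n_mirnas > 0L) {
        m <- 10 * exp(stats::rnorm(spec$n_mirnas, 0, spec$noise_sd))
        names(m) <- mirna_ids
        if (resp) m[repressing] <- m[repressing] / spec$effect_size
      }
      list(sample_id = sprintf("S%03d", i), gene_profile = g,
           mirna_profile = m, true_label = labels[i])
    })
  })
}
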