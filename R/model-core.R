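#' @keywords internal
"_PACKAGE"

## Controlled vocabularies of the model dialect.
SPECIES_KINDS <- c("gene", "mRNA", "protein", "miRNA", "complex",
                   "compound", "pseudo-object", "siRNA")
COMPARTMENTS  <- c("nucleus", "cytoplasm", "membrane", "extracellular")
REACTION_TYPES <- c("transcription", "translation", "decay",
                    "complex-formation", "translocation", "phosphorylation",
                    "dephosphorylation", "activation", "miRNA-binding")

#' Create a species (a token-carrying place of the network)
#'
#' A species is one typed bio-object of the model: a gene, transcript,
#' protein, miRNA, molecular complex, small compound, hallmark accumulator
#' (pseudo-object) or siRNA, located in one cellular compartment and
#' carrying a non-negative token concentration in arbitrary units.
#'
#' @param id Unique identifier within the model.
#' @param kind One of `"gene"`, `"mRNA"`, `"protein"`, `"miRNA"`,
#'   `"complex"`, `"compound"`, `"pseudo-object"`, `"siRNA"`.
#' @param name Display name; defaults to `id`.
#' @param compartment One of `"nucleus"`, `"cytoplasm"`, `"membrane"`,
#'   `"extracellular"`.
#' @param concentration Initial token concentration, must be >= 0.
#' @return An object of class `fnm_species`.
#' @export
species <- function(id, kind, name = id, compartment = "cytoplasm",
                    concentration = 0) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  kind <- match.arg(kind, SPECIES_KINDS)
  compartment <- match.arg(compartment, COMPARTMENTS)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0) {
    stop("species '", id, "': concentration must be a single non-negative number")
  }
  structure(
    list(id = id, name = name, kind = kind, compartment = compartment,
         concentration = as.numeric(concentration)),
    class = "fnm_species"
  )
}

#' Create a reaction (a guarded transition of the network)
#'
#' Reactions consume their reactants and feed their products at a
#' mass-action speed `S = k * prod([reactants]) * prod([enzymes]) *
#' prod(iKd/[I]) / eKd`. Enzymes (including gene/mRNA templates of
#' transcription and translation, see [read_model()]) catalyze without
#' being consumed. Inhibitors scale the speed by their dissociation
#' constant ratio `iKd/[I]`; an inhibitor at zero concentration
#' contributes a factor of 1.
#'
#' @param id Unique reaction identifier.
#' @param rtype One of the typed transitions: `"transcription"`,
#'   `"translation"`, `"decay"`, `"complex-formation"`, `"translocation"`,
#'   `"phosphorylation"`, `"dephosphorylation"`, `"activation"`,
#'   `"miRNA-binding"`.
#' @param reactants,products,enzymes Character vectors of species ids
#'   (each possibly empty; a reaction with neither reactants nor enzymes
#'   never fires).
#' @param inhibitors A data frame with columns `ref` (species id or drug
#'   name), `iKd` (dissociation constant, > 0) and `conc` (fixed inhibitor
#'   concentration for non-species inhibitors such as drugs; `NA` means the
#'   concentration is read from the model state).
#' @param k Positive kinetic parameter.
#' @param eKd Enzymatic dissociation constant; `NA` (the default) behaves
#'   as 1, i.e. plain mass action.
#' @return An object of class `fnm_reaction`.
#' @export
reaction <- function(id, rtype, reactants = character(), products = character(),
                     enzymes = character(), inhibitors = NULL,
                     k = 0.01, eKd = NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  rtype <- match.arg(rtype, REACTION_TYPES)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    stop("reaction '", id, "': kinetic parameter k must be > 0")
  if (!is.na(eKd) && eKd <= 0)
    stop("reaction '", id, "': eKd must be > 0 when present")
  inhibitors <- normalize_inhibitors(inhibitors, id)
  for (s in list(reactants, products, enzymes)) {
    if (anyDuplicated(s))
      stop("reaction '", id, "': duplicated species reference")
  }
  structure(
    list(id = id, rtype = rtype,
         reactants = as.character(reactants),
         products = as.character(products),
         enzymes = as.character(enzymes),
         inhibitors = inhibitors,
         k = as.numeric(k), eKd = as.numeric(eKd)),
    class = "fnm_reaction"
  )
}

normalize_inhibitors <- function(inhibitors, rid) {
  if (is.null(inhibitors) || (is.data.frame(inhibitors) && nrow(inhibitors) == 0L)) {
    return(data.frame(ref = character(), iKd = numeric(), conc = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!is.data.frame(inhibitors) ||
      !all(c("ref", "iKd") %in% names(inhibitors))) {
    stop("reaction '", rid,
         "': inhibitors must be a data frame with columns ref, iKd[, conc]")
  }
  if (is.null(inhibitors$conc)) inhibitors$conc <- NA_real_
  inhibitors <- inhibitors[, c("ref", "iKd", "conc")]
  inhibitors$ref <- as.character(inhibitors$ref)
  inhibitors$iKd <- as.numeric(inhibitors$iKd)
  inhibitors$conc <- as.numeric(inhibitors$conc)
  if (any(!is.finite(inhibitors$iKd)) || any(inhibitors$iKd <= 0))
    stop("reaction '", rid, "': every inhibitor must carry iKd > 0")
  rownames(inhibitors) <- NULL
  inhibitors
}

#' Assemble a molecular model
#'
#' A molecular model is the Petri net: a set of typed species, an ordered
#' list of reactions (always kept sorted lexicographically by reaction id
#' so the sequential simulation is deterministic) and the ids of the
#' pseudo-object species that serve as hallmark readouts (e.g.
#' `"proliferation"`).
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param readouts Character vector of pseudo-object species ids.
#' @param validate Check all cross-references and invariants (default).
#' @return An object of class `molecular_model`.
#' @export
molecular_model <- function(species = list(), reactions = list(),
                            readouts = character(), validate = TRUE) {
  sp_ids <- vapply(species, function(s) s$id, character(1))
  if (anyDuplicated(sp_ids))
    stop("duplicate species id: ", sp_ids[duplicated(sp_ids)][1])
  names(species) <- sp_ids
  rx_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rx_ids))
    stop("duplicate reaction id: ", rx_ids[duplicated(rx_ids)][1])
  names(reactions) <- rx_ids
  reactions <- reactions[order(rx_ids, method = "radix")]
  m <- structure(
    list(species = species, reactions = reactions,
         readouts = as.character(readouts)),
    class = "molecular_model"
  )
  if (validate) validate_model(m)
  m
}

#' Validate a molecular model
#'
#' Checks that every species reference in every reaction resolves, that
#' kinetic parameters and dissociation constants are positive, that
#' concentrations are non-negative, and that every declared readout is a
#' pseudo-object species of the model.
#'
#' @param model A [molecular_model()].
#' @return The model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "molecular_model"))
  sp_ids <- names(model$species)
  for (s in model$species) {
    if (!s$kind %in% SPECIES_KINDS) stop("unknown species kind: ", s$kind)
    if (is.na(s$concentration) || s$concentration < 0)
      stop("species '", s$id, "' has negative concentration")
  }
  for (r in model$reactions) {
    refs <- c(r$reactants, r$products, r$enzymes)
    missing <- setdiff(refs, sp_ids)
    if (length(missing))
      stop("reaction '", r$id, "' references unknown species '",
           missing[1], "'")
    ## inhibitor refs may be drug names, but then a fixed conc must be given
    if (nrow(r$inhibitors)) {
      unresolved <- !(r$inhibitors$ref %in% sp_ids) & is.na(r$inhibitors$conc)
      if (any(unresolved))
        stop("reaction '", r$id, "' inhibitor '",
             r$inhibitors$ref[unresolved][1],
             "' is neither a model species nor carries a fixed concentration")
    }
    if (r$k <= 0) stop("reaction '", r$id, "': k must be > 0")
  }
  bad <- setdiff(model$readouts, sp_ids)
  if (length(bad)) stop("readout '", bad[1], "' is not a model species")
  for (ro in model$readouts) {
    if (model$species[[ro]]$kind != "pseudo-object")
      stop("readout '", ro, "' must be a pseudo-object species")
  }
  invisible(model)
}

#' @export
print.molecular_model <- function(x, ...) {
  cat("A molecular model:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  if (length(x$readouts))
    cat("Hallmark readouts:", paste(x$readouts, collapse = ", "), "\n")
  print(census(x))
  invisible(x)
}

fmt_num <- function(x) {
  ## shortest decimal literal that round-trips the double exactly
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Read a molecular model from XML
#'
#' Parses the package's SBML-like dialect: a `<molecularModel>` root with
#' `<listOfSpecies>` (each `<species>` carrying `id`, `name`, `kind`,
#' `compartment`, `initialConcentration` attributes), `<listOfReactions>`
#' (each `<reaction>` carrying `id`, `rtype`, `k` and optional `eKd`, with
#' `<reactant>`, `<product>`, `<enzyme>` and `<inhibitor>` children
#' referencing species by `ref`; inhibitors carry `iKd` and, for drugs, a
#' fixed `conc`), and `<listOfReadouts>`. Genes acting as transcription
#' templates are listed among the enzymes so they are never consumed.
#'
#' @param xml_source Path to an XML file, or a string of XML.
#' @return A validated [molecular_model()] with reactions sorted by id.
#' @export
read_model <- function(xml_source) {
  doc <- tryCatch(xml2::read_xml(xml_source),
                  error = function(e) stop("malformed model XML: ",
                                           conditionMessage(e), call. = FALSE))
  root <- xml2::xml_name(doc)
  if (root != "molecularModel")
    stop("expected <molecularModel> root, found <", root, ">")
  sp_nodes <- xml2::xml_find_all(doc, "./listOfSpecies/species")
  species_list <- lapply(sp_nodes, function(nd) {
    a <- xml2::xml_attrs(nd)
    kind <- a[["kind"]]
    if (!kind %in% SPECIES_KINDS)
      stop("unknown species kind '", kind, "' for species '", a[["id"]], "'")
    species(id = a[["id"]],
            name = if ("name" %in% names(a)) a[["name"]] else a[["id"]],
            kind = kind,
            compartment = a[["compartment"]],
            concentration = as.numeric(a[["initialConcentration"]]))
  })
  rx_nodes <- xml2::xml_find_all(doc, "./listOfReactions/reaction")
  reactions_list <- lapply(rx_nodes, function(nd) {
    a <- xml2::xml_attrs(nd)
    rtype <- a[["rtype"]]
    if (!rtype %in% REACTION_TYPES)
      stop("unknown reaction type '", rtype, "' for reaction '", a[["id"]], "'")
    ref_of <- function(tag) xml2::xml_attr(xml2::xml_find_all(nd, tag), "ref")
    inh_nodes <- xml2::xml_find_all(nd, "./inhibitor")
    inhibitors <- NULL
    if (length(inh_nodes)) {
      inhibitors <- data.frame(
        ref = xml2::xml_attr(inh_nodes, "ref"),
        iKd = as.numeric(xml2::xml_attr(inh_nodes, "iKd")),
        conc = as.numeric(xml2::xml_attr(inh_nodes, "conc")),
        stringsAsFactors = FALSE
      )
    }
    reaction(id = a[["id"]], rtype = rtype,
             reactants = ref_of("./reactant"),
             products = ref_of("./product"),
             enzymes = ref_of("./enzyme"),
             inhibitors = inhibitors,
             k = as.numeric(a[["k"]]),
             eKd = if ("eKd" %in% names(a)) as.numeric(a[["eKd"]]) else NA_real_)
  })
  readouts <- xml2::xml_attr(
    xml2::xml_find_all(doc, "./listOfReadouts/readout"), "ref")
  molecular_model(species_list, reactions_list, readouts)
}

#' Write a molecular model to XML
#'
#' Serializes a model to the dialect read by [read_model()]. Numeric
#' attributes are written as shortest decimal literals that round-trip the
#' underlying double exactly, so `read_model(write_model(m))` reproduces
#' `m` field by field and serialization is byte-stable.
#'
#' @param model A [molecular_model()].
#' @param destination File path, or `NULL` to return the XML as a string.
#' @return The destination path (invisibly), or the XML string.
#' @export
write_model <- function(model, destination = NULL) {
  validate_model(model)
  doc <- xml2::xml_new_root("molecularModel")
  losp <- xml2::xml_add_child(doc, "listOfSpecies")
  for (s in model$species) {
    xml2::xml_add_child(losp, "species", id = s$id, name = s$name,
                        kind = s$kind, compartment = s$compartment,
                        initialConcentration = fmt_num(s$concentration))
  }
  lorx <- xml2::xml_add_child(doc, "listOfReactions")
  for (r in model$reactions) {
    attrs <- list(id = r$id, rtype = r$rtype, k = fmt_num(r$k))
    if (!is.na(r$eKd)) attrs$eKd <- fmt_num(r$eKd)
    nd <- do.call(xml2::xml_add_child, c(list(lorx, "reaction"), attrs))
    for (a in r$reactants) xml2::xml_add_child(nd, "reactant", ref = a)
    for (p in r$products) xml2::xml_add_child(nd, "product", ref = p)
    for (e in r$enzymes) xml2::xml_add_child(nd, "enzyme", ref = e)
    if (nrow(r$inhibitors)) {
      for (i in seq_len(nrow(r$inhibitors))) {
        attrs <- list(ref = r$inhibitors$ref[i],
                      iKd = fmt_num(r$inhibitors$iKd[i]))
        if (!is.na(r$inhibitors$conc[i]))
          attrs$conc <- fmt_num(r$inhibitors$conc[i])
        do.call(xml2::xml_add_child, c(list(nd, "inhibitor"), attrs))
      }
    }
  }
  loro <- xml2::xml_add_child(doc, "listOfReadouts")
  for (ro in model$readouts) xml2::xml_add_child(loro, "readout", ref = ro)
  if (is.null(destination)) {
    as.character(doc)
  } else {
    xml2::write_xml(doc, destination)
    invisible(destination)
  }
}

#' Partition a model into per-kind component arrays
#'
#' Splits the species of a model into one array per kind (gene array,
#' mRNA array, protein array, ...) preserving model order, and the
#' reactions into one array per reaction type. The species arrays are
#' jointly exhaustive and mutually exclusive.
#'
#' @param model A [molecular_model()].
#' @return A list with `species` (named list of character vectors of
#'   species ids, one per kind) and `reactions` (likewise per rtype).
#' @export
partition_by_type <- function(model) {
  validate_model(model)
  kinds <- vapply(model$species, function(s) s$kind, character(1))
  sp <- lapply(SPECIES_KINDS,
               function(k) names(model$species)[kinds == k])
  names(sp) <- SPECIES_KINDS
  rtypes <- vapply(model$reactions, function(r) r$rtype, character(1))
  rx <- lapply(REACTION_TYPES,
               function(t) names(model$reactions)[rtypes == t])
  names(rx) <- REACTION_TYPES
  list(species = sp, reactions = rx)
}

#' Component and reaction census of a model
#'
#' Counts species per kind and reactions per type, the style of summary
#' used to characterize large curated signaling models.
#'
#' @param model A [molecular_model()].
#' @return An object of class `model_census`: a list with `species`
#'   (named integer vector per kind), `reactions` (per rtype),
#'   `n_species` and `n_reactions` totals.
#' @export
census <- function(model) {
  part <- partition_by_type(model)
  sp <- vapply(part$species, length, integer(1))
  rx <- vapply(part$reactions, length, integer(1))
  structure(list(species = sp, reactions = rx,
                 n_species = sum(sp), n_reactions = sum(rx)),
            class = "model_census")
}

#' @export
print.model_census <- function(x, ...) {
  cat("Species (", x$n_species, "):\n", sep = "")
  for (k in names(x$species))
    if (x$species[[k]] > 0) cat(sprintf("  %-14s %d\n", k, x$species[[k]]))
  cat("Reactions (", x$n_reactions, "):\n", sep = "")
  for (t in names(x$reactions))
    if (x$reactions[[t]] > 0) cat(sprintf("  %-18s %d\n", t, x$reactions[[t]]))
  invisible(x)
}

#' Test two models for equality
#'
#' Field-by-field comparison of species (id, name, kind, compartment,
#' concentration), reactions (all parameters including inhibitor tables)
#' and readouts.
#'
#' @param a,b Two [molecular_model()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
model_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0)) ||
    identical(unclass(a), unclass(b))
}
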