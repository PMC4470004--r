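## miRNA identifiers arrive in mixed styles ("hsa-miR-21", "mir-21",
## "miR-21"); identity is decided after lowercasing and stripping the
## species prefix.
normalize_mirna <- function(x) sub("^hsa-", "", tolower(x))

#' Load a miRNA-target table (miRT)
#'
#' Reads a tab-separated table of experimentally validated miRNA-target
#' interactions with columns `gene_id` (Ensembl gene ID), `mirna_id` and
#' `pubmed`, into a keyed array: one entry per distinct target gene,
#' holding the list of (miRNA, PubMed reference) records. Duplicate
#' identical rows are dropped with a warning.
#'
#' @param tsv_source Path to the TSV file (with header).
#' @return An object of class `mirt_table`: a named list of data frames
#'   (columns `mirna_id`, `pubmed`), keyed by Ensembl gene ID.
#' @export
load_mirt <- function(tsv_source) {
  tab <- utils::read.delim(tsv_source, stringsAsFactors = FALSE,
                           colClasses = "character")
  mirt_table(tab)
}

#' Construct a miRT table from a data frame
#'
#' @param tab Data frame with columns `gene_id`, `mirna_id`, `pubmed`.
#' @return An object of class `mirt_table` (see [load_mirt()]).
#' @export
mirt_table <- function(tab) {
  need <- c("gene_id", "mirna_id", "pubmed")
  if (!is.data.frame(tab) || !all(need %in% names(tab)))
    stop("miRT table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  if (anyDuplicated(tab)) {
    warning("miRT table contains duplicate rows; deduplicated")
    tab <- unique(tab)
  }
  if (any(!nzchar(tab$gene_id)) || any(!nzchar(tab$mirna_id)))
    stop("miRT table: gene_id and mirna_id must be non-empty")
  out <- lapply(split(tab[, c("mirna_id", "pubmed")], tab$gene_id),
                function(d) { rownames(d) <- NULL; d })
  structure(out[unique(tab$gene_id)], class = "mirt_table")
}

#' Load a TF-miRNA regulation table (TFmiR)
#'
#' Reads a TransmiR-style tab-separated table with columns `mirna_id`,
#' `tf_gene_id` (Ensembl ID of the transcription factor gene),
#' `regulation` (`"activation"` or `"repression"`) and `pubmed`, into a
#' keyed array: one entry per miRNA holding its transcription-factor
#' records.
#'
#' @param tsv_source Path to the TSV file (with header).
#' @return An object of class `tfmir_table`: a named list of data frames
#'   (columns `tf_gene_id`, `regulation`, `pubmed`), keyed by miRNA ID.
#' @export
load_tfmir <- function(tsv_source) {
  tab <- utils::read.delim(tsv_source, stringsAsFactors = FALSE,
                           colClasses = "character")
  tfmir_table(tab)
}

#' Construct a TFmiR table from a data frame
#'
#' @param tab Data frame with columns `mirna_id`, `tf_gene_id`,
#'   `regulation`, `pubmed`.
#' @return An object of class `tfmir_table` (see [load_tfmir()]).
#' @export
tfmir_table <- function(tab) {
  need <- c("mirna_id", "tf_gene_id", "regulation", "pubmed")
  if (!is.data.frame(tab) || !all(need %in% names(tab)))
    stop("TFmiR table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  bad <- which(!tab$regulation %in% c("activation", "repression"))
  if (length(bad))
    stop("TFmiR table row ", bad[1], ": regulation '",
         tab$regulation[bad[1]], "' is not 'activation' or 'repression'")
  if (any(!nzchar(tab$mirna_id)))
    stop("TFmiR table: mirna_id must be non-empty")
  out <- lapply(split(tab[, c("tf_gene_id", "regulation", "pubmed")],
                      tab$mirna_id),
                function(d) { rownames(d) <- NULL; d })
  structure(out[unique(tab$mirna_id)], class = "tfmir_table")
}

#' Splice miRNA regulation into a molecular model (the miR-add-on)
#'
#' Iterates the model's gene array; a gene matches when its Ensembl ID is
#' a key of the miRNA-target table *and* the model contains that gene's
#' mRNA (located as the mRNA-kind product of a transcription reaction the
#' gene drives). For every new mature miRNA implied by the matches, the
#' extension adds a miRNA-gene species (nucleus), a nuclear miRNA
#' species, a cytoplasmic miRNA species, a transcription reaction from
#' miRNA gene to nuclear miRNA (carrying as enzymes any activating
#' transcription factors from the TF-miRNA table that exist in the model,
#' and repressing ones as reaction inhibitors with a dissociation
#' constant of 1 token unit), a nucleus-to-cytoplasm translocation, and a
#' decay reaction for the cytoplasmic miRNA. For every (miRNA, target
#' mRNA) pair it adds one silenced miRNA:mRNA complex species, one
#' miRNA-binding reaction consuming cytoplasmic miRNA plus target mRNA
#' into that complex (RISC simplified to a single sequestration step),
#' and a decay reaction for the complex, so silencing is a persistent
#' sink rather than a transient one. Each mature miRNA is one shared
#' species across all its targets, so targets compete for a common pool.
#' Pre-existing target-gene transcription/translation/decay reactions are
#' never duplicated, and the extension is idempotent: re-running it adds
#' nothing.
#'
#' New objects carry deterministic ids (`miRgene:<mirna>`,
#' `miR:<mirna>:nuc`, `miR:<mirna>:cyt`, `cx:<mirna>:<mRNA-id>` and
#' reaction ids `rx:tc:`, `rx:tl:`, `rx:dec:`, `rx:bind:`, `rx:dec:cx:`)
#' so the output is reproducible byte for byte.
#'
#' @param model A [molecular_model()].
#' @param mirt A [load_mirt()] table.
#' @param tfmir A [load_tfmir()] table (may be empty).
#' @param k Kinetic parameter of created production/transport/binding
#'   reactions (default 0.01).
#' @param fast_k Kinetic parameter of created translocation and decay
#'   reactions (default 0.5; transport and turnover much faster than
#'   synthesis, so the nuclear pool, the free cytoplasmic miRNA and the
#'   silencing complex all equilibrate strictly below their firing
#'   guards instead of saturating them into limit cycles).
#' @param tf_eKd Enzymatic dissociation constant attached to miRNA
#'   transcription when TF enzymes are present (default 100 token units,
#'   the typical expression scale, so template-times-TF products stay on
#'   the same token scale as first-order rates).
#' @return The extended, validated [molecular_model()].
#' @export
extend_model <- function(model, mirt, tfmir = NULL, k = 0.01,
                         fast_k = 0.5, tf_eKd = 100) {
  validate_model(model)
  stopifnot(inherits(mirt, "mirt_table"))
  if (is.null(tfmir)) tfmir <- structure(list(), class = "tfmir_table")
  stopifnot(inherits(tfmir, "tfmir_table"))

  sp <- model$species
  rx <- model$reactions
  sp_ids <- names(sp)
  gene_ids <- sp_ids[vapply(sp, function(s) s$kind, character(1)) == "gene"]

  ## gene -> mRNA ids via the transcription reactions the gene drives
  mrnas_of <- function(gid) {
    hits <- character()
    for (r in rx) {
      if (r$rtype != "transcription") next
      if (!(gid %in% r$enzymes || gid %in% r$reactants)) next
      prods <- r$products
      prods <- prods[vapply(sp[prods], function(s) s$kind == "mRNA",
                            logical(1))]
      hits <- c(hits, prods)
    }
    unique(hits)
  }

  mirt_keys <- tolower(names(mirt))
  tfmir_keys <- normalize_mirna(names(tfmir))
  new_sp <- list()
  new_rx <- list()
  have_sp <- function(id) id %in% sp_ids || id %in% names(new_sp)
  add_sp <- function(s) new_sp[[s$id]] <<- s
  add_rx <- function(r) new_rx[[r$id]] <<- r

  for (gid in gene_ids) {
    ki <- match(tolower(gid), mirt_keys)
    if (is.na(ki)) next
    targets <- mrnas_of(gid)
    if (!length(targets)) {
      warning("gene '", gid,
              "' matches the miRT table but has no mRNA in the model; skipped")
      next
    }
    entries <- mirt[[ki]]
    for (j in seq_len(nrow(entries))) {
      mid <- normalize_mirna(entries$mirna_id[j])
      mg <- paste0("miRgene:", mid)
      mn <- paste0("miR:", mid, ":nuc")
      mc <- paste0("miR:", mid, ":cyt")
      if (!have_sp(mg)) {
        add_sp(species(mg, "gene", name = mid, compartment = "nucleus"))
        add_sp(species(mn, "miRNA", name = paste0(mid, " (nuclear)"),
                       compartment = "nucleus"))
        add_sp(species(mc, "miRNA", name = paste0(mid, " (cytoplasmic)"),
                       compartment = "cytoplasm"))
        ## TF-driven transcription of the miRNA gene
        enz <- mg
        inh <- NULL
        ti <- match(mid, tfmir_keys)
        if (!is.na(ti)) {
          tfs <- tfmir[[ti]]
          present <- tfs$tf_gene_id %in% sp_ids
          act <- tfs$tf_gene_id[present & tfs$regulation == "activation"]
          rep_ <- tfs$tf_gene_id[present & tfs$regulation == "repression"]
          enz <- c(enz, unique(act))
          if (length(rep_))
            inh <- data.frame(ref = unique(rep_), iKd = 1, conc = NA_real_,
                              stringsAsFactors = FALSE)
        }
        add_rx(reaction(paste0("rx:tc:", mid), "transcription",
                        products = mn, enzymes = enz, inhibitors = inh,
                        k = k,
                        eKd = if (length(enz) > 1L) tf_eKd else NA_real_))
        add_rx(reaction(paste0("rx:tl:", mid), "translocation",
                        reactants = mn, products = mc, k = fast_k))
        add_rx(reaction(paste0("rx:dec:", mid), "decay",
                        reactants = mc, k = fast_k))
      }
      for (tg in targets) {
        cx <- paste0("cx:", mid, ":", tg)
        if (have_sp(cx)) next
        add_sp(species(cx, "complex",
                       name = paste0(mid, ":", tg, " silenced"),
                       compartment = "cytoplasm"))
        add_rx(reaction(paste0("rx:bind:", mid, ":", tg), "miRNA-binding",
                        reactants = c(mc, tg), products = cx, k = k))
        add_rx(reaction(paste0("rx:dec:cx:", mid, ":", tg), "decay",
                        reactants = cx, k = fast_k))
      }
    }
  }
  molecular_model(c(sp, new_sp), c(rx, new_rx), model$readouts)
}
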