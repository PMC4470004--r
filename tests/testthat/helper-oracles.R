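## Independent oracles used by the test suite. These are deliberately
## naive, direct transcriptions of the published rules, written without
## reference to the package's engine internals.

## --- naive token-game simulator ---------------------------------------
## Sequentially evaluates S = k * [reactants] * [enzymes] * (iKd/[I]) / eKd
## and fires when product < reactant and S < 0.75 * reactant (limiting
## species on both sides), mutating concentrations in place.

naive_speed <- function(r, conc) {
  s <- r$k
  for (a in r$reactants) s <- s * conc[[a]]
  for (e in r$enzymes) s <- s * conc[[e]]
  if (nrow(r$inhibitors)) {
    for (j in seq_len(nrow(r$inhibitors))) {
      ci <- r$inhibitors$conc[j]
      if (is.na(ci)) ci <- conc[[r$inhibitors$ref[j]]]
      s <- s * (if (ci > 0) r$inhibitors$iKd[j] / ci else 1)
    }
  }
  if (!is.na(r$eKd)) s <- s / r$eKd
  s
}

naive_trajectory <- function(model, n_steps) {
  conc <- vapply(model$species, function(s) s$concentration, numeric(1))
  names(conc) <- names(model$species)
  rs <- model$reactions[order(names(model$reactions), method = "radix")]
  out <- matrix(NA_real_, n_steps + 1L, length(conc),
                dimnames = list(NULL, names(conc)))
  out[1L, ] <- conc
  for (t in seq_len(n_steps)) {
    for (r in rs) {
      src <- if (length(r$reactants)) r$reactants else r$enzymes
      if (!length(src)) next
      a <- min(conc[src])
      p <- if (length(r$products)) min(conc[r$products]) else 0
      s <- naive_speed(r, conc)
      if (p < a && s < 0.75 * a) {
        for (pp in r$products) conc[[pp]] <- conc[[pp]] + s
        for (aa in r$reactants) conc[[aa]] <- conc[[aa]] - s
      }
    }
    out[t + 1L, ] <- conc
  }
  out
}

## --- random small nets -------------------------------------------------
## Arbitrary wiring over 3-6 species and up to 5 reactions, with random
## kinds, kinetic parameters spanning the firing-cap boundary, optional
## enzymes, species- and drug-style inhibitors and eKd values.

## length-safe sampler (sample() misbehaves on length-1 vectors)
samp <- function(x, n) x[sample.int(length(x), min(n, length(x)))]

rand_net <- function(seed) {
  withr::with_seed(seed, {
    n_sp <- sample(3:6, 1)
    sp_ids <- sprintf("X%d", seq_len(n_sp))
    sp <- lapply(sp_ids, function(id)
      species(id, samp(SPECIES_KINDS, 1),
              compartment = samp(COMPARTMENTS, 1),
              concentration = round(stats::runif(1, 0, 20), 3)))
    n_rx <- sample(1:5, 1)
    rx <- lapply(seq_len(n_rx), function(i) {
      repeat {
        reactants <- samp(sp_ids, sample(0:2, 1))
        enzymes <- samp(setdiff(sp_ids, reactants), sample(0:2, 1))
        if (length(reactants) || length(enzymes)) break
      }
      products <- samp(setdiff(sp_ids, reactants), sample(0:2, 1))
      inhibitors <- NULL
      u <- stats::runif(1)
      if (u < 0.2) {
        inhibitors <- data.frame(ref = samp(sp_ids, 1),
                                 iKd = round(stats::runif(1, 0.5, 5), 3),
                                 conc = NA_real_)
      } else if (u < 0.4) {
        inhibitors <- data.frame(ref = "drugX",
                                 iKd = round(stats::runif(1, 0.5, 5), 3),
                                 conc = round(stats::runif(1, 0.1, 10), 3))
      }
      reaction(sprintf("R%02d", i), samp(REACTION_TYPES, 1),
               reactants = reactants, products = products,
               enzymes = enzymes, inhibitors = inhibitors,
               k = round(stats::runif(1, 0.001, 0.5), 4),
               eKd = if (stats::runif(1) < 0.3)
                 round(stats::runif(1, 0.5, 20), 3) else NA_real_)
    })
    molecular_model(sp, rx)
  })
}

## --- reference TMM -----------------------------------------------------
## Straightforward transcription of the published trimmed-mean-of-M-values
## factor: reference column by upper quartile closest to the mean, log2
## ratios M and average log intensities A on library-size-scaled counts,
## double trimming (30% on M, 5% on A, rank-based), precision weights
## from the asymptotic binomial variances, factors normalized to unit
## geometric mean.

ref_tmm_factors <- function(counts, ref_col = NULL) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  counts <- counts[rowSums(counts > 0) > 0L, , drop = FALSE]
  if (is.null(ref_col)) {
    f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    ref_col <- which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; ref <- counts[, ref_col]
    nO <- lib[j]; nR <- lib[ref_col]
    logR <- log2((obs / nO) / (ref / nR))
    absE <- (log2(obs / nO) + log2(ref / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep], na.rm = TRUE) /
         sum(1 / v[keep], na.rm = TRUE))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

## random count matrix with heterogeneous library sizes
rand_counts <- function(seed, n_features = 200, n_samples = 4) {
  withr::with_seed(seed, {
    mu <- stats::rexp(n_features, 1 / 50)
    depth <- stats::runif(n_samples, 0.5, 2)
    m <- sapply(depth, function(d) stats::rpois(n_features, mu * d))
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_features)),
                        sprintf("s%d", seq_len(n_samples)))
    m
  })
}

## --- assorted fixture builders ----------------------------------------

one_gene_cascade <- function(gene_conc = 20) {
  molecular_model(
    list(species("ENSG00000000777", "gene", compartment = "nucleus",
                 concentration = gene_conc),
         species("mRNA:g", "mRNA"),
         species("prot:g", "protein")),
    list(reaction("tc:g", "transcription", enzymes = "ENSG00000000777",
                  products = "mRNA:g", k = 0.01),
         reaction("dec:m", "decay", reactants = "mRNA:g", k = 0.1),
         reaction("tl:g", "translation", enzymes = "mRNA:g",
                  products = "prot:g", k = 0.01),
         reaction("dec:p", "decay", reactants = "prot:g", k = 0.05)))
}

toy_3sp_xml <- function() {
  paste0('<molecularModel><listOfSpecies>',
         '<species id="g1" name="G1" kind="gene" compartment="nucleus" ',
         'initialConcentration="10"/>',
         '<species id="m1" name="M1" kind="mRNA" compartment="cytoplasm" ',
         'initialConcentration="0"/>',
         '<species id="p1" name="P1" kind="protein" compartment="cytoplasm" ',
         'initialConcentration="0"/>',
         '</listOfSpecies><listOfReactions>',
         '<reaction id="r1" rtype="transcription" k="0.01">',
         '<product ref="m1"/><enzyme ref="g1"/></reaction>',
         '</listOfReactions><listOfReadouts/></molecularModel>')
}

## closed-form extension delta: 3 species + 3 reactions per new mature
## miRNA, 1 complex species + binding + complex decay per (miRNA, target
## mRNA) pair, computed here combinatorially and independently of
## extend_model's own bookkeeping
expected_deltas <- function(model, mirt) {
  gkinds <- vapply(model$species, function(s) s$kind, character(1))
  genes <- names(model$species)[gkinds == "gene"]
  pairs <- list()
  for (g in intersect(genes, names(mirt))) {
    mrnas <- unique(unlist(lapply(model$reactions, function(r) {
      if (r$rtype != "transcription") return(NULL)
      if (!(g %in% r$enzymes || g %in% r$reactants)) return(NULL)
      kk <- vapply(model$species[r$products], function(s) s$kind,
                   character(1))
      r$products[kk == "mRNA"]
    })))
    if (!length(mrnas)) next
    for (m in tolower(mirt[[g]]$mirna_id))
      pairs[[length(pairs) + 1L]] <- expand.grid(mirna = m, target = mrnas,
                                                 stringsAsFactors = FALSE)
  }
  if (!length(pairs)) return(list(species = 0L, reactions = 0L))
  pairs <- unique(do.call(rbind, pairs))
  M <- length(unique(pairs$mirna))
  T_ <- nrow(pairs)
  list(species = 3L * M + T_, reactions = 3L * M + 2L * T_)
}

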