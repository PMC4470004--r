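Package: fluxnetmir
Title: Petri-Net Signaling Models with miRNA Regulation and Flux
    Comparative Analysis for Drug-Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and simulates token-based (Petri-net) models of
    molecular signaling networks. Provides an SBML-like XML dialect for
    typed species (gene, mRNA, protein, miRNA, complex, compound,
    pseudo-object, siRNA) and typed reactions; a miR-add-on algorithm
    that splices experimentally validated miRNA-target and TF-miRNA
    regulation into an existing model; initialization of gene and
    miRNA-gene concentrations from TMM-normalized expression profiles;
    a deterministic guarded firing-rule simulator with mass-action
    speeds and dissociation-constant inhibitor modeling; Flux
    Comparative Analysis comparing hallmark readouts between untreated
    and drug-treated states; kinase-inhibitor drug specifications with
    published dissociation constants; sensitivity scoring, responder
    classification, pooled within-treatment correlation and ROC/AUC;
    and seeded synthetic model/cohort generators for end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    edgeR,
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
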