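Package: domevol
Title: Ancestral Protein Domain Repertoires by Dollo Parsimony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs ancestral protein-domain repertoires (domainomes)
    on a rooted species tree under Dollo parsimony. Filters per-genome
    domain-hit tables (HMMER3 domtblout or minimal TSV) by gathering /
    noise / trusted bit-score cutoffs or uniform E-value thresholds,
    removes excluded (viral / phage / transposon) domains, and resolves
    overlapping hits by lowest E-value. Builds taxon-by-domain
    presence/absence matrices, infers per-branch domain gains and losses,
    compares alternative tree topologies by parsimony cost, maps domains
    to Gene Ontology terms via pfam2go, computes functional profiles and
    per-branch functional flux, and tests gained or lost domain sets for
    GO term enrichment with term-for-term, topology-elim, and parent-child
    algorithms. Includes a synthetic-data generator (single-gain /
    multi-loss domain histories, noisy hit tables, layered GO DAGs with
    planted enrichment) so the whole pipeline is testable without external
    genome or Pfam downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    igraph,
    xml2,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
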