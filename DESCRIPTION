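Package: porecap
Title: Nucleotide Capture Analysis for Protein Nanopore Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for nucleotide-capture simulations of the
    alpha-hemolysin protein nanopore. Classifies release trajectories of a
    mononucleotide into captured, possible-capture and failed-capture
    outcomes against the N17 C-alpha ring, computes per-residue van der
    Waals contact frequencies and residence durations, estimates capture
    probabilities with binomial standard errors, and fits the linear
    capture-probability model in release height and lateral translation.
    Includes a surrogate trajectory generator (overdamped Langevin descent
    into a simplified pore geometry) and a Bernoulli outcome generator for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
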