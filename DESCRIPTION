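Package: hifflux
Title: Heterogeneous Inbred Family Fine Mapping and 15N Nitrogen Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the two computational halves of a heterogeneous inbred
    family (HIF) fine-mapping and nitrogen-flux study in Arabidopsis thaliana.
    The genetic half detects recombinants in selfed progeny genotyped over a
    residual heterozygous region, represents recombination breakpoints as
    marker-bounded uncertainty intervals, tests recombinant progeny for
    phenotype segregation, and refines the candidate interval by closed/open
    interval algebra over marker positions. The isotope half implements the
    15N tracer bookkeeping used in pulse-labeling experiments: atom percent,
    enrichment, organ nitrogen quantities, allocation fractions, harvest
    index, nitrogen harvest indices, nitrogen remobilization efficiency (NRE)
    and nitrogen uptake efficiency (NUpE), plus root-to-shoot translocation
    profiles and genotype contrasts (ANOVA, Tukey HSD letters, least-square
    means). Leaf-senescence utilities score yellow-leaf fractions, group
    leaves by rank, and detect the onset of chlorophyll decline relative to
    flower bud emergence. Forward simulators with known ground truth emulate
    both experimental designs (Haldane crossover model; organ-level tracer
    partitioning) so that every analysis stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
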