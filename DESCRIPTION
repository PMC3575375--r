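Package: coalexact
Title: Exact Coalescent Calculations for Infinite-Sites and
    Infinite-Alleles Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Exact calculations in coalescent theory for samples under
    the infinite-sites and infinite-alleles mutation models.  Tests
    binary haplotype data for a perfect phylogeny (Gusfield's algorithm
    and the four-gamete test), builds the rooted gene tree of mutations,
    and solves the exact probability recursion over ancestral
    configurations for a given population mutation rate.  Counts and
    enumerates the ancestral configurations and genealogies of a sample,
    profiles the recursion graph by level, evaluates the Ewens sampling
    formula for allele frequency spectra, and ships a forward coalescent
    simulator that doubles as a Monte-Carlo oracle for the exact
    recursion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    withr
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
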