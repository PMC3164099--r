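Package: ampliclone
Title: Germline and Somatic Variation in Multigene-Family Amplicon Clones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies cloned cDNA/gDNA amplicon sequences from tandemly
    duplicated multigene families (such as mussel antimicrobial-peptide
    genes) into per-individual germline "basic" sequences, somatic point
    mutants and recombinant (chimeric) clones; quantifies somatic mutation
    and recombination rates; computes domain-partitioned nucleotide
    diversity and neutrality statistics (Watterson's theta, pi, haplotype
    diversity, Tajima's D, Fu and Li's D, Hudson-Kaplan Rm, Nei-Gojobori
    Ka/Ks); infers minimum locus number from intron fragment-analysis
    genotypes and full-sib family transmission; and simulates datasets
    with known ground truth for all of the above.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
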