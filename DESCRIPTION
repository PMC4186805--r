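Package: mitocomp
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.9.0
Authors@R: person("Mitocomp", "Developers", role = c("aut", "cre"),
    email = "mitocomp@example.org")
Description: Tools for comparative mitogenomics of insects: reading and
    writing annotated mitochondrial genomes, nucleotide composition and
    AT/GC strand-skew statistics, codon-position partitioned composition
    and codon usage, protein-guided codon alignment, substitution-rate
    estimation (p-distance, Kimura two-parameter, Dayhoff/PAM amino-acid
    distance, Nei-Gojobori Ka/Ks), structure discovery in the AT-rich
    control region (tandem repeats, cross-taxon conserved segments,
    poly(N) runs, stem-loop hairpins), GC-content versus rate regression,
    and a fully seeded mitogenome evolution simulator with planted ground
    truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    phangorn,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
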