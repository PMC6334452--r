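Package: crispredit
Title: Windowed Quantification of CRISPR and Base-Editing Outcomes in Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies genome-editing outcomes from targeted amplicon
    sequencing reads. Reads are quality-filtered, globally aligned to a
    reference amplicon, and consolidated into alleles by their sequence
    within a window centered on the predicted Cas9 cleavage site. Alleles
    are translated in genomic context and classified as reference, silent,
    missense, in-frame indel, frameshift, or nonsense, with dedicated
    support for cytidine base-editor (BE3-style) C-to-T conversion
    profiling within the editing window, off-target site panels with
    treated-versus-control exact tests, and detection of translocation
    junction-spanning reads between two cut loci. A read simulator with
    per-read ground truth supports parameter-recovery and calibration
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
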