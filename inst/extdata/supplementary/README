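Place a plain-text TSV export of the study-scale glycoproteome rollup here as
glycoproteome.tsv to enable the supplementary-scale acceptance checks
(mono-glycosylated fraction 43%, cohort occupancy 44.4%, receptor rate 37.7%).

Required columns (tab-separated, '#' comments allowed):
  accession          protein identifier
  stoichiometry      detected N-glycans on the protein
  sequon_count       putative NXS/T sequons on the protein
  functional_class   receptor/transporter/enzyme/miscellaneous/unclassified

The source tables were published as binary XLS supplementary files only, so
they are not bundled; without this file the corresponding acceptance test
reports a failure by design.
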