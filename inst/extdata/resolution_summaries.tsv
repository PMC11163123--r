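# Published per-resolution average consistency percentages for the
# duplicate-sample and tool-vs-tool evaluations (unweighted means across the
# loci each comparison covers); the overall averages quoted alongside them
# are the arithmetic means of these three values.
dataset	mean_field1	mean_field2	mean_field3	n_loci
hlahd_vs_hlatwin_panel	96.45	95.27	94.59	11
panel_vs_research_exome_duplicates	96.18	90.95	89.14	11
genome_vs_research_exome_duplicates	97.51	94.64	93.49	29
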