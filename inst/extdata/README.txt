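Small synthetic example dataset produced by triohet's own generator
(trio_sim_config(seed = 7) with 30 genes, 8 splice events, one muscle
trio of 3 replicates per role). Entirely simulated; no real sequencing
data. Used by the package documentation to demonstrate the file formats:

  example_counts.tsv   gene x sample integer counts
  example_samples.tsv  sample sheet (sample_id, species_role, ...)
  example_events.tsv   splice events with I:/S: junction-count columns
  example_reads.bed    long reads as BED12 intron chains
  example_sets.gmt     two synthetic gene sets
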