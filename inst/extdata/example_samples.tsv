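sample_id	species_role	species_name	tissue	replicate
muscle_hyb_1	hybrid	mule	muscle	1
muscle_hyb_2	hybrid	mule	muscle	2
muscle_hyb_3	hybrid	mule	muscle	3
muscle_pat_1	paternal_parent	donkey	muscle	1
muscle_pat_2	paternal_parent	donkey	muscle	2
muscle_pat_3	paternal_parent	donkey	muscle	3
muscle_mat_1	maternal_parent	horse	muscle	1
muscle_mat_2	maternal_parent	horse	muscle	2
muscle_mat_3	maternal_parent	horse	muscle	3
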