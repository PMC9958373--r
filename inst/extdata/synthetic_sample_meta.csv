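"sample_id","mouse_id","organ","cohort"
"m01_bm","m01","bone_marrow","3m"
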