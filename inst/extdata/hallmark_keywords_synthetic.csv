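"hallmark","keyword"
"immune_dysregulation","immune"
"immune_dysregulation","inflammat"
"immune_dysregulation","leukocyte"
"immune_dysregulation","cytokine"
"immune_dysregulation","interferon"
"stress_response","stress"
"stress_response","dna damage"
"stress_response","heat shock"
"stress_response","apoptot"
"stress_response","unfolded protein"
"gene_expression_dysregulation","transcription"
"gene_expression_dysregulation","chromatin"
"gene_expression_dysregulation","mrna processing"
"gene_expression_dysregulation","gene expression"
"gene_expression_dysregulation","rna splicing"
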