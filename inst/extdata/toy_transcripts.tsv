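transcript_id	strand	exons	cds_start	cds_end	complete
TOYPLUS	+	101-130	4	27	TRUE
TOYMINUS	-	201-210;221-230	1	20	FALSE
TOYMINUS_CDS	-	1001-1012;1021-1032	1	24	TRUE
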