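!Series_title	"Synthetic mini series-matrix fixture (3 samples, 4 probes) for ingestion tests"
!Series_geo_accession	"SYNTHETIC"
!Sample_title	"sample A"	"sample B"	"sample C"
!Sample_geo_accession	"GSM000001"	"GSM000002"	"GSM000003"
!Sample_characteristics_ch1	"class: healthy"	"class: sle_active"	"class: sle_inactive"
!series_matrix_table_begin
"ID_REF"	"GSM000001"	"GSM000002"	"GSM000003"
"P_CD2"	6.10	2.35	5.20
"P_CD3"	5.80	2.90	4.95
"P_CD5"	4.25	1.60	3.80
"P_UNKNOWN"	0.50	0.45	0.55
!series_matrix_table_end
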