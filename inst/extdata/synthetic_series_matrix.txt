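!Series_title	"synthetic example cohort (generated by pairwave)"
!Sample_title	"ctrl_001"	"ctrl_002"	"ctrl_003"	"case_001"	"case_002"	"case_003"
!Sample_characteristics_ch1	"group: control"	"group: control"	"group: control"	"group: case"	"group: case"	"group: case"
!series_matrix_table_begin
"ID_REF"	"ctrl_001"	"ctrl_002"	"ctrl_003"	"case_001"	"case_002"	"case_003"
"g0001"	8.686	9.465	10.18	15.13	14.96	14.64
"g0002"	9.034	9.435	9.912	15.09	14.9	14.49
"g0003"	9.354	8.265	8.619	13.83	12.14	12.78
"g0004"	9.311	7.712	8.482	11.76	10.59	10.87
"g0005"	7.372	8.207	9.223	12.85	13.38	12.37
"g0006"	7.092	8.285	9.34	13.55	13.8	12.65
"g0007"	7.953	8.058	10.29	11.89	14.1	13.02
"g0008"	7.774	8.521	9.061	2.889	4.543	5.573
!series_matrix_table_end
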