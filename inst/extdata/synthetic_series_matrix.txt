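!Series_title	"synthetic inguinal fat development series (fixture)"
!Series_summary	"synthetic data generated for parser testing; not real measurements"
!Sample_title	"Control_d5_rep1"	"Control_d5_rep2"	"Control_d5_rep3"	"LUN_d5_rep1"	"LUN_d5_rep2"	"LUN_d5_rep3"	"pooled reference RNA"
!Sample_geo_accession	"GSM00001"	"GSM00002"	"GSM00003"	"GSM00004"	"GSM00005"	"GSM00006"	"GSM00007"
!series_matrix_table_begin
"ID_REF"	"GSM00001"	"GSM00002"	"GSM00003"	"GSM00004"	"GSM00005"	"GSM00006"	"GSM00007"
"probe_0001"	5123.4	7180.6	3315.6	2616.7	3069.6	880.0	4795.6
"probe_0002"	4375.3	5442.6	777.9	2720.7	3754.9	1996.6	4037.9
"probe_0003"	3197.9	2842.6	2385.6	2088.6	1230.6	1129.4	1400.9
"probe_0004"	4251.8	2262.8	861.0	3661.3	6086.3	1800.4	788.1
"probe_0005"	2229.9	3562.2	988.6	1236.3	7670.8	936.4	3050.9
"probe_0006"	3288.3	4635.2	1006.6	1023.3	3947.9	2608.4	5626.1
"probe_0007"	1493.6	5150.8	1426.7	3511.9	3135.1	10626.9	3133.8
"probe_0008"	4410.3	1926.2	1490.0	3066.3	9094.4	2479.3	9217.1
"probe_0009"	2227.7	998.3	11218.5	2098.3	2951.3	1884.3	9908.4
"probe_0010"	1058.5	9136.6	2633.2	4106.5	5127.9	4675.9	1101.5
"probe_0011"	1641.5	8941.4	844.5	4760.6	2850.0	2450.5	4134.0
"probe_0012"	6230.7	4273.6	4911.2	4383.9	3323.6	15222.4	2506.6
"probe_0013"	5431.9	2651.7	3882.3	1565.8	13248.8	2438.3	5769.7
"probe_0014"	400.7	3302.6	2167.9	3798.9	7472.4	270.7	6237.4
"probe_0015"	261.7	475.4	1255.0	1539.3	1405.3	1146.2	2107.0
"probe_0016"	2981.6	999.0	2803.0	3338.1	2837.0	6458.4	3153.3
"probe_0017"	2175.0	2545.3	1957.8	5389.9	2206.4	1153.4	6354.5
"probe_0018"	738.0	3147.8	4076.7	9027.6	3525.4	1510.6	4145.2
"probe_0019"	4442.2	3204.8	1729.6	1795.7	5241.5	2149.1	681.7
"probe_0020"	3702.5	3859.2	1637.7	3607.9	5022.4	690.8	3257.5
!series_matrix_table_end
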