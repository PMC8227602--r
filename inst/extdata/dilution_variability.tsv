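sample_id	msih_fraction_pct	ihc_status	BAT-25	BAT-26	D5S346	D2S123	D17S250	pub_n_unstable	pub_nci_status	pub_max_variability	pub_msi_score	pub_score_status
100% MSI-H	100	MSI-H	7	0	36	0	13	3	MSI-H	36	56	MSI-H
80% MSI-H	80	MSI-H	42	7	23	0	0	3	MSI-H	42	73	MSI-H
60% MSI-H	60	MSI-H	11	0	21	6	8	4	MSI-H	21	46	MSI-H
40% MSI-H	40	MSI-H	11	0	18	0	22	3	MSI-H	22	51	MSI-H
20% MSI-H	20	MSI-H	6	0	17	0	35	3	MSI-H	35	58	MSI-H
10% MSI-H	10	MSI-H	0	5	3	0	17	3	MSI-H	17	25	MSI-H
5% MSI-H	5	MSI-H	10	0	0	0	18	2	MSI-H	18	29	MSI-H
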