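lipid_class	category	n_species	conc_mean_control	conc_sd_control	conc_mean_case	conc_sd_case	conc_species_down	conc_species_up	comp_mean_control	comp_sd_control	comp_mean_case	comp_sd_case	comp_species_down	comp_species_up
TG	glycerolipid	518	29.687	7.193	63.494	12.995	0	370	40.292	6.894	59.986	5.720	82	109
DG	glycerolipid	58	0.921	0.162	1.212	0.201	1	17	1.256	0.169	1.165	0.209	13	4
MG	glycerolipid	22	0.162	0.062	0.155	0.076	0	1	0.228	0.108	0.150	0.071	0	0
PC	phospholipid	72	19.502	2.593	16.940	2.959	7	0	26.799	3.913	16.381	3.477	0	5
PE	phospholipid	93	16.657	2.093	14.721	2.332	9	4	22.857	2.975	14.161	2.388	3	9
PI	phospholipid	7	0.252	0.042	0.233	0.042	0	0	0.348	0.069	0.222	0.029	1	1
LPC	phospholipid	16	0.572	0.136	0.502	0.090	1	0	0.788	0.195	0.483	0.088	0	0
LPE	phospholipid	11	0.071	0.019	0.059	0.017	0	0	0.097	0.027	0.056	0.013	0	0
Cer	sphingolipid	12	0.126	0.027	0.107	0.021	1	0	0.173	0.039	0.102	0.014	1	2
HexCer	sphingolipid	10	0.025	0.002	0.021	0.003	3	2	0.034	0.004	0.020	0.005	1	4
LacCer	sphingolipid	10	0.003	0.000	0.003	0.000	0	1	0.004	0.001	0.003	0.001	2	1
dhCer	sphingolipid	10	0.022	0.002	0.019	0.003	2	1	0.030	0.004	0.018	0.002	0	2
SM	sphingolipid	12	2.178	0.281	1.964	0.311	1	0	2.992	0.429	1.887	0.293	0	2
CE	sterol	26	3.018	0.847	5.678	1.892	0	23	4.102	1.033	5.365	1.461	5	11
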