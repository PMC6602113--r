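protein_id	abundance	n_cys	deg_rate_per_min
P0001	2183.40068670944	10	0.00176165469527199
P0002	197.990516969416	6	0.00212436080611877
P0003	1232.268984098	9	0.000828837493107615
P0004	880.625192774406	8	0.000612275253621089
P0005	367.894368945281	5	0.000558018237435789
P0006	22.9569731420364	6	0.000464383620717
P0007	331.966839464536	6	0.000720322818848512
P0008	216.495959462905	2	0.00433779152520737
P0009	1185.69803703268	9	0.00144217113744543
P0010	491.306812927621	3	0.0036373210934657
P0011	542.090641379656	4	0.00320396932125492
P0012	334.322254311332	8	0.00304842404794742
P0013	717.376193314383	5	0.00299514382670425
P0014	712.678560760543	5	0.00107406145473411
P0015	21.9207375702093	4	0.00703353507084816
P0016	7542.11200035656	2	0.004791418729419
P0017	2520.89051678229	6	0.00185941612279949
P0018	1385.89550881707	5	0.00192452060726238
P0019	299.069812686243	5	0.000950968487267159
P0020	2814.03716684419	6	0.00334476426239707
P0021	610.786369846087	8	0.00850997581266509
P0022	781.123223211455	4	0.00544578611536208
P0023	123.929388933461	6	0.00124971833874391
P0024	9013.62338071624	7	0.00565668652324876
P0025	1074.98876712412	3	0.0012663112766944
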