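sample	x
sample_001	0.67
sample_002	0.0364
sample_003	0.8338
sample_004	0.2939
sample_005	0.7767
sample_006	0.134
sample_007	0.5683
sample_008	0.4845
sample_009	0.6644
sample_010	0.1773
sample_011	0.9869
sample_012	0.4333
sample_013	0.4474
sample_014	0.7816
sample_015	0.877
sample_016	0.7756
sample_017	0.6366
sample_018	0.0877
sample_019	0.3489
sample_020	0.4678
sample_021	0.6933
sample_022	0.182
sample_023	0.9188
sample_024	0.2626
sample_025	0.7521
sample_026	0.7524
sample_027	0.8869
sample_028	0.8557
sample_029	0.0702
sample_030	0.7907
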