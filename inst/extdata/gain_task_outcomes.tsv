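markers	species	trait	mean	lower	upper	sd	eq	noi	sup
High	Maize	Days to tassel	0.017	0.013	0.021	TRUE	FALSE	TRUE	TRUE
High	Maize	Germination count	0.001	-0.003	0.005	FALSE	TRUE	TRUE	FALSE
High	Maize	Number of leaves	0.005	0.000	0.011	TRUE	FALSE	TRUE	FALSE
High	Maize	Plant height	0.018	0.013	0.022	TRUE	FALSE	TRUE	TRUE
High	Rice	Grain length	0.002	-0.003	0.008	FALSE	TRUE	TRUE	FALSE
High	Rice	Grain width	-0.005	-0.008	-0.003	TRUE	TRUE	TRUE	FALSE
High	Rice	Grain weight	0.010	0.006	0.013	TRUE	FALSE	TRUE	FALSE
High	Rice	Days to heading	0.002	0.000	0.004	FALSE	TRUE	TRUE	FALSE
Low	Maize	Days to tassel	0.037	0.032	0.041	TRUE	FALSE	TRUE	TRUE
Low	Maize	Germination count	0.004	-0.001	0.008	FALSE	TRUE	TRUE	FALSE
Low	Maize	Number of leaves	0.015	0.009	0.021	TRUE	FALSE	TRUE	FALSE
Low	Maize	Plant height	0.018	0.014	0.022	TRUE	FALSE	TRUE	TRUE
Low	Rice	Grain length	0.019	0.012	0.025	TRUE	FALSE	TRUE	TRUE
Low	Rice	Grain width	0.007	0.004	0.010	TRUE	FALSE	TRUE	FALSE
Low	Rice	Grain weight	0.019	0.015	0.023	TRUE	FALSE	TRUE	TRUE
Low	Rice	Days to heading	0.009	0.006	0.012	TRUE	FALSE	TRUE	FALSE
Low	Wheat	Yield 1	0.100	0.084	0.116	TRUE	FALSE	TRUE	TRUE
Low	Wheat	Yield 2	0.105	0.087	0.123	TRUE	FALSE	TRUE	TRUE
Low	Wheat	Yield 3	0.079	0.064	0.094	TRUE	FALSE	TRUE	TRUE
Low	Wheat	Yield 4	0.008	-0.010	0.024	FALSE	FALSE	TRUE	FALSE
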