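snp_id	effect_allele	other_allele	log_or
rs_sim_1	T	G	0.16377385484648926
rs_sim_2	A	G	0.01746834112239256
rs_sim_3	T	G	0.12203658433703636
rs_sim_4	A	C	0.1115094290565567
rs_sim_5	T	C	0.2970781858123814
rs_sim_6	G	C	0.1340809538180416
rs_sim_7	G	T	0.1647954197623151
rs_sim_8	A	C	0.04608389363436467
rs_sim_9	A	T	0.03436896350766531
rs_sim_10	C	G	0.032796478979744324
rs_sim_11	A	G	0.20884414810467966
rs_sim_12	A	G	0.01653603297950114
rs_sim_13	T	G	0.004526218621904007
rs_sim_14	T	A	0.01190637139129367
rs_sim_15	C	G	0.10285703054211744
rs_sim_16	A	T	0.004929341764145442
rs_sim_17	G	T	0.05765615052918858
rs_sim_18	C	A	0.18508241550650362
rs_sim_19	A	C	0.11535866041301117
rs_sim_20	C	T	0.1491761025344134
rs_sim_21	A	G	0.10110357108089972
rs_sim_22	G	A	0.1597927745947059
rs_sim_23	T	G	0.04693388702857876
rs_sim_24	C	G	0.05315228560278505
rs_sim_25	A	C	0.033152600328071095
rs_sim_26	A	G	0.047962797083309
rs_sim_27	T	C	0.08027444254241171
rs_sim_28	A	T	0.1199074541372461
rs_sim_29	T	G	0.0990883032537059
rs_sim_30	G	T	0.03398482672021412
rs_sim_31	G	T	0.04659848150789394
rs_sim_32	C	T	0.006815425118999565
rs_sim_33	T	C	0.0019301148074095215
rs_sim_34	A	T	0.04966656927485086
rs_sim_35	C	T	0.3510797256557851
rs_sim_36	T	C	0.04698266833183864
rs_sim_37	C	T	0.02779347468295728
rs_sim_38	G	C	0.16682249081170875
rs_sim_39	T	G	0.20535213000258526
rs_sim_40	A	T	0.02237754395600843
rs_sim_41	T	G	0.01761791098269171
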