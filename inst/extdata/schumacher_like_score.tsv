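#score_name=schumacher_like
#weight_scale=OR
variant_id	chrom	pos	effect_allele	other_allele	European
rsS00001	1	1000137	C	T	0.922440365929044
rsS00002	2	1000274	A	T	1.00116881107716
rsS00003	3	1000411	G	C	1.01424845406035
rsS00004	4	1000548	T	G	0.923335879224393
rsS00005	5	1000685	T	C	0.865334805008914
rsS00006	6	1000822	T	A	0.956478163366461
rsS00007	7	1000959	C	G	1.42458853651147
rsS00008	8	1001096	T	C	0.968223768919421
rsS00009	9	1001233	T	C	0.975410256257816
rsS00010	10	1001370	A	G	0.945214296534702
rsS00011	11	1001507	C	A	1.03285325039444
rsS00012	12	1001644	G	T	1.01493225660146
rsS00013	13	1001781	T	C	1.03760697262687
rsS00014	14	1001918	G	A	1.0000378087834
rsS00015	15	1002055	A	C	0.97594670265774
rsS00016	16	1002192	G	T	1.06276607344748
rsS00017	17	1002329	G	C	1.17798373561611
rsS00018	18	1002466	A	T	1.09241764009638
rsS00019	19	1002603	A	T	1.12784005446515
rsS00020	20	1002740	T	C	1.13543532187968
rsS00021	21	1002877	A	C	1.01294518033113
rsS00022	22	1003014	C	T	0.99768461394708
rsS00023	1	1003151	G	C	1.0647885146498
rsS00024	2	1003288	A	G	1.07606939513974
rsS00025	3	1003425	A	G	1.25782860299125
rsS00026	4	1003562	A	C	1.0616331429722
rsS00027	5	1003699	G	T	0.90473221884121
rsS00028	6	1003836	C	A	0.936147421340113
rsS00029	7	1003973	C	G	0.974338755731348
rsS00030	8	1004110	G	A	0.919392865546639
rsS00031	9	1004247	A	G	1.02989998501974
rsS00032	10	1004384	T	A	1.09414658374052
rsS00033	11	1004521	G	A	1.04648622382681
rsS00034	12	1004658	G	A	0.957941051542615
rsS00035	13	1004795	G	T	1.04148797190611
rsS00036	14	1004932	T	C	1.05054734230782
rsS00037	15	1005069	T	G	1.00366198224284
rsS00038	16	1005206	A	T	1.06864162266992
rsS00039	17	1005343	T	G	1.07120265420132
rsS00040	18	1005480	G	A	1.10007861288679
rsS00041	19	1005617	G	A	0.899934811069985
rsS00042	20	1005754	T	G	1.0185862842797
rsS00043	21	1005891	G	C	1.07307610188663
rsS00044	22	1006028	T	C	1.01706302103336
rsS00045	1	1006165	C	G	0.887694492654098
rsS00046	2	1006302	G	T	1.02451061386615
rsS00047	3	1006439	C	G	0.927946782667997
rsS00048	4	1006576	G	T	1.038306258513
rsS00049	5	1006713	T	G	0.984339069318337
rsS00050	6	1006850	A	T	0.835649619501911
rsS00051	7	1006987	G	A	0.957708765225691
rsS00052	8	1007124	A	G	1.12500899691023
rsS00053	9	1007261	C	A	1.08162435009641
rsS00054	10	1007398	T	G	1.05053600234402
rsS00055	11	1007535	C	A	0.952179900814817
rsS00056	12	1007672	G	C	0.900892900509908
rsS00057	13	1007809	G	A	0.854845184235201
rsS00058	14	1007946	T	C	1.0364852286493
rsS00059	15	1008083	C	G	1.06721630770815
rsS00060	16	1008220	G	C	0.997816045567352
rsS00061	17	1008357	C	G	1.13004498591137
rsS00062	18	1008494	T	A	0.931504516913358
rsS00063	19	1008631	C	G	1.0798430885303
rsS00064	20	1008768	C	G	0.991339834420564
rsS00065	21	1008905	T	A	0.988795631917361
rsS00066	22	1009042	C	G	0.923193566681627
rsS00067	1	1009179	C	A	0.983363887180462
rsS00068	2	1009316	C	T	1.14675877791754
rsS00069	3	1009453	A	C	0.930580206003965
rsS00070	4	1009590	A	C	1.05125177181884
rsS00071	5	1009727	G	C	1.10385448983093
rsS00072	6	1009864	A	C	1.0489343971242
rsS00073	7	1010001	C	A	0.951133757504258
rsS00074	8	1010138	T	G	0.992929305311332
rsS00075	9	1010275	A	G	1.18355842401439
rsS00076	10	1010412	T	G	1.09726943688886
chr10_ins_77	11	1010549	C	A	0.932363131410531
rsS00078	12	1010686	T	G	1.09713742923516
rsS00079	13	1010823	T	C	0.938923257042797
rsS00080	14	1010960	C	G	0.950395023404629
rsS00081	15	1011097	C	A	1.03202054955524
rsS00082	16	1011234	C	G	1.05031362384296
rsS00083	17	1011371	G	T	1.06557617482743
rsS00084	18	1011508	A	C	0.998424403076486
rsS00085	19	1011645	A	G	1.00997535641798
rsS00086	20	1011782	A	T	1.13926371238364
rsS00087	21	1011919	C	G	1.02379607948096
rsS00088	22	1012056	T	A	0.877167789132685
rsS00089	1	1012193	A	T	1.12802670495265
rsS00090	2	1012330	T	G	1.08890097679015
rsS00091	3	1012467	T	C	1.1889140629391
rsS00092	4	1012604	T	C	0.962907693915319
rsS00093	5	1012741	G	A	0.986177548382882
rsS00094	6	1012878	G	C	0.817154594174052
rsS00095	7	1013015	C	A	1.00465619106655
rsS00096	8	1013152	A	G	1.06622442556071
rsS00097	9	1013289	T	C	0.919140767062688
rsS00098	10	1013426	T	G	0.938497066476985
rsS00099	11	1013563	T	A	0.993438229610198
rsS00100	12	1013700	T	G	0.890035849870912
rsS00101	13	1013837	T	C	0.929644606178665
rsS00102	14	1013974	A	G	1.00463257795784
rsS00103	15	1014111	G	C	0.932833086809838
rsS00104	16	1014248	G	C	0.949693069479842
rsS00105	17	1014385	T	C	1.03340630323176
rsS00106	18	1014522	C	G	1.06772151565396
rsS00107	19	1014659	T	G	0.95468727603876
rsS00108	20	1014796	T	C	1.08990505851146
rsS00109	21	1014933	A	T	0.949038817537739
rsS00110	22	1015070	G	A	0.962135055896486
rsS00111	1	1015207	A	G	0.979728378676533
rsS00112	2	1015344	A	T	0.993694563012588
rsS00113	3	1015481	T	G	1.06144180277824
rsS00114	4	1015618	A	G	1.12004326285899
rsS00115	5	1015755	C	A	1.06949683508967
rsS00116	6	1015892	T	A	1.03534167902276
rsS00117	7	1016029	A	C	0.863956807516476
rsS00118	8	1016166	C	T	0.988501222068199
rsS00119	9	1016303	C	G	1.03220742424744
rsS00120	10	1016440	C	A	1.11416655538827
rsS00121	11	1016577	C	G	1.03134976339724
rsS00122	12	1016714	T	A	0.973036582671128
rsS00123	13	1016851	G	C	0.97926091712624
rsS00124	14	1016988	G	T	1.07913307168365
rsS00125	15	1017125	C	T	0.909465115526229
rsS00126	16	1017262	C	A	0.86258050368066
rsS00127	17	1017399	T	G	1.09114551719959
rsS00128	18	1017536	A	G	0.97481854915169
rsS00129	19	1017673	G	A	1.06225419377442
rsS00130	20	1017810	C	A	0.961173068218637
rsS00131	21	1017947	C	T	0.911847927706918
rsS00132	22	1018084	C	A	1.08634820859395
rsS00133	1	1018221	G	C	0.862571539483995
rsS00134	2	1018358	T	G	0.996897752691609
rsS00135	3	1018495	T	C	0.907890150421692
rsS00136	4	1018632	T	A	1.0390948101718
rsS00137	5	1018769	T	G	1.03618810337688
rsS00138	6	1018906	T	G	1.0872919000135
rsS00139	7	1019043	C	T	0.935703023635254
rsS00140	8	1019180	C	A	0.940800513291952
rsS00141	9	1019317	A	C	1.02911038905188
rsS00142	10	1019454	C	T	0.977838136623119
rsS00143	11	1019591	T	C	0.864607854931943
rsS00144	12	1019728	T	C	1.0476302418007
rsS00145	13	1019865	A	G	1.09241357729216
rsS00146	14	1020002	T	C	1.06602023033792
rsS00147	15	1020139	A	G	1.10319101946215
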