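gene	C1	C2	C3	C4	C5	C6	C7	C8
g_A1	14.301183951234071	18.15728276536468	12.733109600327982	25.343869753652093	18.82609347442156	12.029710404490448	15.456427952471664	20.621431465645315
g_A2	16.046644152629202	18.08843395168551	14.52660114388779	27.916476297085737	23.055375089886123	15.164767193721012	22.381400907131308	22.96243391339757
g_B1	21.23277435254358	17.590680648629593	25.668005562444357	22.730222369555545	18.010251282961388	9.976376979841454	23.764350256253486	20.313264777648374
g_B2	17.775870683492307	12.969845530902033	24.431095103616435	18.953602071492078	12.149941778817928	5	22.383785133907537	14.525297629493272
g_bio	5.575495393030792	9.630670839836945	7.356957207688577	11.998024746131378	8.156935134081722	6.33887136348541	9.254629779714682	11.817866064468184
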