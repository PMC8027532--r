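label	x	y	region	hemisphere
E01	-0.130349633481274	0.119410941924505	central	left
E02	0.0267685519936974	-0.305013843332005	parieto_occipital	midline
E03	0.240506577206469	0.313698240862822	frontal	right
E04	-0.460557560773298	-0.0814661476599304	central	left
E05	0.447468817967925	-0.284643034248842	central	right
E06	-0.152206515378494	0.566200650543901	frontal	left
E07	-0.293771739120683	-0.565639607253602	parieto_occipital	left
E08	0.643109328427142	0.234862495281792	central	right
E09	-0.673726809006696	0.278104632873412	frontal	left
E10	0.326595273371957	-0.697915129088843	parieto_occipital	right
E11	0.242447640085584	0.77296128092999	frontal	right
E12	-0.733518491205677	-0.425088958994876	parieto_occipital	left
E13	0.863267578191376	-0.189786955409471	central	right
E14	-0.528290114043951	0.751438324417533	frontal	left
E15	-0.122338531898399	-0.944078007165162	parieto_occipital	left
E16	0.752606526384513	0.634297577201298	frontal	right
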