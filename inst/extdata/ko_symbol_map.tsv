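ko	symbol
K00928	lysC
K00133	asd
K00836	ectB
K06718	ectA
K06720	ectC
K00626	phaA
K00626	atoB
K00023	phaB
K03821	phaC
K01652	E2.2.1.6L
K01653	E2.2.1.6S
K11258	ilvM
K01575	alsD
K00004	BDH
K18009	butA
K03366	budC
K01641	mvaS
K00054	mvaA
K00869	mvk
K00938	pmk
K01597	mvd
K01823	idi
K01662	dxs
K00099	dxr
K00991	ispD
K00919	ispE
K00920	ispF
K03526	ispG
K03527	ispH
K00795	ispA
K13789	crtE
K02291	crtB
K10027	crtI
K06443	crtY
K15746	crtZ
K02292	crtW
K06444	lcyE
K15747	cyp97A
K09837	cyp97C
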