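# intrinsic Boltzmann weights, one rotamer per line
0.004898843437340743
0.014880426663483168
0.005808518348455910
0.041406424810139800
0.038735467037921599
0.006458716127517634
0.018488288516312242
0.024748325712125166
0.065844031374547043
0.015405193737502453
0.025244559228478781
0.108706681339889616
0.001756546705048252
0.008289132645871907
0.009756182413807423
0.004796997678741883
0.012811196884267989
0.021074280691130470
0.008078283215367299
0.018303492858329874
0.007992169570203714
0.005506778072932988
0.011900550807888863
0.060894797443980922
0.008554530141102983
0.005082003914210074
0.008099739590696991
0.018767419219190621
0.003005905207601002
0.025128631068447847
0.005889119485642588
0.016108535561782274
0.007438968804800543
0.007774667235789593
0.032636408733626984
0.000970998223300664
0.082093615627665636
0.008897193709970936
0.006136659993072045
0.097642739553374908
0.025408016225810758
0.023749382298209536
0.003145914645891136
0.010796562295264545
0.052478903540353818
0.008408199602908849
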