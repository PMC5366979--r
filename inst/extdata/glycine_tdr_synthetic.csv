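# Synthetic 3 mol% glycine TDR spectrum: three-Debye fixture model,
# 3% multiplicative noise, seed 42. Generated with dielax::simulate_spectrum().
frequency_hz,eps_real,eps_imag
5e+08,123.374684029899,8.35055886846648
629374896.322225,115.692448855479,11.5639700439642
792225520.241226,117.746417777338,13.4708058572003
997213709.331285,116.921458401907,15.5100744095598
1255242549.84296,113.728049898522,19.2831222282311
1580036299.33332,108.946001824897,23.2324930096777
1988870364.15653,110.381254648984,26.741168953427
2503490158.47872,101.14584670271,27.5880614929581
3151267717.87253,102.875780408083,30.1823099987541
3966657586.4392,92.1918490337421,31.159579887834
4993029414.42189,90.8195831109827,36.0909036075926
6284974740.0712,87.4154696141441,37.8421886009355
7911210650.84026,72.0896015909127,42.2455668707722
9958234766.31174,66.837938092442,45.3677873324003
12534925947.1997,58.1391944402375,47.620140729222
15778335436.8512,49.5224358170114,45.4681978946825
19860976459.4111,38.550219950794,45.1754072580203
2.5e+10,27.7019484207833,38.8261162499972
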