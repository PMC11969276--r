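name,cas,pka_dmso,pred_correlation,pred_nh,pred_universal,recommended,uncertainty,ga_exp,ga_calc,n_hbd,n_xh_xso2,n_n
"Pyrrole",109-97-7,23.0,34.9,35.3,35.5,35.2,0.5,1468;1472,1482,1,1,1
"Pyrazole",288-13-1,19.8,31.6,31.8,32.1,31.8,0.5,1449,1463,1,1,2
"Imidazole",288-32-4,18.6,30.4,30.6,30.9,30.6,0.5,1434,1443,1,1,2
"1,2,4-Triazole",288-88-0,14.75,26.5,26.5,26.8,26.6,0.5,1410,1419,1,1,3
"1H-1,2,3-Triazole",288-36-8,13.9,25.6,25.6,25.9,25.7,0.5,1419,1412,1,1,3
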