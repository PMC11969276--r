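name,pka_mecn,pred_nh,diff_nh,pred_universal,diff_universal
"2,3,5,6-Cl4-Aniline",33.51,33.30,-0.21,33.09,-0.42
"4-CF3SO2-Aniline",33.11,34.10,0.99,33.94,0.83
"4-NO2-Aniline",32.58,32.90,0.32,32.98,0.40
"(2-NO2-C6H4)(Ph)NH",31.79,31.20,-0.59,31.49,-0.30
"Carbazole",31.74,32.20,0.46,32.23,0.49
"4-Cl-2-NO2-Aniline",31.06,30.90,-0.16,30.85,-0.21
"1,3-Ph2-Urea",30.96,31.60,0.64,30.74,-0.22
"4-NH2-C5F4N",30.12,30.70,0.58,30.64,0.52
"Indazole",29.79,30.20,0.41,30.43,0.64
"2,5-Cl2-4-NO2-Aniline",29.20,29.40,0.20,29.26,0.06
"(4-NO2-C6H4)(Ph)NH",28.87,28.85,-0.02,28.99,0.12
"4-NO2-1-Naphthalenamine",28.85,29.40,0.55,29.26,0.41
"Benzimidazole",27.92,28.40,0.48,28.51,0.59
"2,4-(NO2)2-Aniline",27.64,27.60,-0.04,27.66,0.02
"1H-Benzotriazole",22.98,23.62,0.64,23.74,0.76
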