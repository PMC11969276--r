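name,cas,pka_mecn,pka_dmso,pka_h2o,ga_exp,ga_calc,n_hbd,n_xh_xso2,n_n
"2,3,5,6-Cl4-Aniline",3481-20-7,33.51,21.0,19.22,,1426,2,2,1
"4-CF3SO2-Aniline",473-27-8,33.11,21.8,,,1400,2,2,1
"2,3,4,5,6-Cl5-Aniline",527-20-8,32.79,,,,1415,2,2,1
"Indole",120-72-9,32.78,20.95,16.97,1431;1440,1441,1,1,1
"2-NO2-Aniline",88-74-4,32.63,,17.7,,1436,2,2,2
"N-Me-4-NO2-Aniline",100-15-2,32.62,,18.2,,1421,1,1,2
"4-NO2-Aniline",100-01-6,32.58,20.9,18.2,1407,1421,2,2,2
"(2-NO2-C6H4)(Ph)NH",119-75-5,31.79,19.2,18.0,,1421,1,1,2
"2-MeO-Carbazole",6933-49-9,31.78,,,,1417,1,1,1
"Carbazole",86-74-8,31.74,19.9,16.7,1412,1420,1,1,1
"2-NH2-4-NO2-Aniline",99-56-9,31.75,,,,1416,4,2,3
"3-Cl-4-NO2-Aniline",825-41-2,31.53,,,,1403,2,2,2
"4-Cl-2-NO2-Aniline",89-63-4,31.06,18.9,17.1,,1412,2,2,2
"5-Cl-2-NO2-Aniline",1635-61-6,31.03,,,,1411,2,2,2
"1,3-Ph2-Urea",102-07-8,30.96,19.6,,,1396,2,1,2
"(2-NO2-C6H4)(4-Cl-C6H4)NH",23008-56-2,30.92,,,,1402,1,1,2
"2-Cl-6-NO2-Aniline",769-11-9,30.84,,,,1423,2,2,2
"7-Azaindole",271-63-6,30.79,,12.1,,1437,1,1,2
"4-Azaindole",272-49-1,30.49,,15.5;16.1,,1422,1,1,2
"2-Cl-4-NO2-Aniline",121-87-9,30.38,,18.06,,1398,2,2,2
"Benzo[c]carbazole",205-25-4,30.33,,,,1401,1,1,1
"3-MeCOO-Indole",608-08-2,30.2,,,,1427,1,1,1
"Benzo[a]carbazole",239-01-0,30.20,,,,1400,1,1,1
"7-NO2-Indole",6960-42-5,30.12,,,,1415,1,1,2
"4-NH2-C5F4N",1682-20-8,30.12,18.7,,1392,1407,2,2,2
"5-Azaindole",271-34-1,30.06,,,,1414,1,1,2
"Indolo[2,3-a]carbazole",60511-85-5,29.9,,,,1387,2,1,2
"(5-Cl-2-NO2-C6H3)(Ph)NH",25781-92-4,29.88,,,,1397,1,1,2
"Indazole",271-44-3,29.79,18.2,13.86,1425,1433,1,1,2
"6-Azaindole",271-29-4,29.75,,,,1413,1,1,2
"2,3-Cl2-6-NO2-Aniline",65078-77-5,29.43,,,,1403,2,2,2
"Norharman",244-63-3,29.33,,14.53,,1398,1,1,2
"2,4-Cl2-6-NO2-Aniline",2683-43-4,29.26,,16.39,,1401,2,2,2
"2,5-Cl2-4-NO2-Aniline",6627-34-5,29.20,17.4,16.05,,1380,2,2,2
"(4-NO2-C6H4)(Ph)NH",836-30-6,28.87,16.85,15.6,1374,1384,1,1,2
"4-NO2-1-Naphthalenamine",776-34-1,28.85,17.4,,,1385,2,2,2
"2,6-Cl2-4-NO2-Aniline",99-30-9,28.30,,15.55,,1387,2,2,2
"Benzimidazole",51-17-2,27.92,16.4,12.86,,1403,1,1,2
"2,4-(NO2)2-Aniline",97-02-9,27.64,15.9,15.0,,1367,2,2,3
"1H-Benzotriazole",95-14-7,22.98,11.92,8.57,1384,1383,1,1,3
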