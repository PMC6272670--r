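compound,rt_min,measured_mz,adduct,error_ppm,formula,fragments,identity
15,12.349,329.0865,[M+H]+,-2.43,C14H16O9,293.0663;275.0549;263.0555;247.0610;233.0442,bergenin
16,13.795,501.1551,[M+Na]+,-5.79,C20H30O13,411.1230;369.1147,kelampayoside A
17,15.450,561.1963,[M+Na]+,2.63,C26H34O12,381.1310,tanegoside A
18,16.775,721.2315,[M+Na]+,-0.69,C32H42O17,559.1771;397.1249;159.0419,nortrachelogenin 4-4'-di-O-glucoside
19,21.416,705.2371,[M+Na]+,0,C32H42O16,543.1870;381.1335;159.0435,matairesinol 4-4'-di-O-glucoside
20,21.416,721.2309,[M+Na]+,-1.53,C32H42O17,559.1743;397.1295;159.0421,nortrachelogenin 4'-O-gentiobioside
21,22.976,559.1792,[M+Na]+,0.18,C26H32O12,397.1328;159.0415,nortrachelogenin 4-O-glucoside
22,30.531,573.1968,[M+Na]+,3.49,C27H34O12,411.1426,4-demethyltraxillaside
23,32.928,545.1992,[M+Na]+,-1.28,C26H34O11,383.1596;159.0366,dihydrodehydrodiconiferyl alcohol-9-O-glucoside
24,39.434,587.2125,[M+Na]+,3.58,C28H36O12,425.1583;159.0412,traxillageside
25,42.339,579.1719,[M+H]+,0.86,C27H30O14,433.1125;271.0605,apigenin 7-O-neospheroside
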