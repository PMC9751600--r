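genotype,release_year,hsi_2020_2021,hsi_2021_2022
Chenab-70,1970,0.3,0.1
Pari-73,1973,0.4,0.2
Pak-81,1981,0.4,0.3
MH-21,2021,0.2,0.4
Punjab-76,1976,0.03,0.3
NIFA-Aman,2016,0.2,0.2
NUWYT-63,,0.4,0.3
Swabi-1,2020,0.2,0.2
Nisnan-21,2021,0.4,0.3
Frontana,1940,0.4,0.3
Amin-2000,2000,0.4,0.3
Pirsabak-2004,2004,0.2,0.4
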