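"databank_code","energy_kcal","energy_kJ","carbohydrate_g","protein_g","fat_g","vitamin_C_mg","iron_mg"
"DB_BRD1",235,983.24,46,8,2,0,1.1
"DB_BRD2",265,1108.76,43,10.5,5.5,0,1.6
"DB_BRD3",218,912.112,41,9,2.5,0,2.4
"DB_SPR1",744,3112.896,0.6,0.5,82,0,0.02
"DB_SPR2",630,2635.92,1,0.2,70,0,0.05
"DB_MTF1",109,456.056,0,25,0.6,0,1
"DB_MTF2",107,447.688,1,18,3.3,0,0.7
"DB_MTF3",170,711.28,0,27,6.6,0,0.7
"DB_CHD1",416,1740.544,0.1,25.4,34.9,0,0.3
"DB_EXT1",15,62.76,3,0.7,0.1,2.8,0.3
"DB_EXT2",18,75.312,3.9,0.9,0.2,13.7,0.27
"DB_EXT3",15,62.76,2.9,1.4,0.2,9.2,0.86
"DB_SLD1",86,359.824,19,3.2,1.2,6.8,0.52
"DB_SLD2",41,171.544,9.6,0.9,0.2,5.9,0.3
"DB_SAU1",680,2845.12,1.7,1.1,75,0,0.2
"DB_SAU2",102,426.768,24,1.2,0.1,4,0.3
"DB_SAU3",348,1456.032,16.7,1.5,31,0,0.2
"DB_FRT1",52,217.568,13.8,0.3,0.2,6,0.12
"DB_FRT2",89,372.376,22.8,1.1,0.3,8.7,0.26
"DB_CNF1",334,1397.456,77,4.2,0.2,0,0.3
"DB_STP1",270,1129.68,36,3.9,12.4,9,0.8
"DB_STP2",378,1581.552,84,7,0.9,0,8
"DB_STP3",116,485.344,15.3,4.8,4.4,0.7,0.6
"DB_DSH1",104,435.136,17.5,3.5,2.2,5.5,0.9
"DB_SUG1",400,1673.6,100,0,0,0,0
"DB_DRK1",42,175.728,10.6,0,0,0,0
"DB_DRK2",1,4.184,0.2,0.1,0,0,0
"DB_DRK3",2,8.368,0.3,0.2,0,0,0
"DB_DRK4",44,184.096,10.4,0.5,0.1,39,0.2
"DB_DRK5",48,200.832,4.8,3.4,1.8,0.9,0.02
"DB_ALC1",36,150.624,2.6,0,0,0,0.1
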