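# Abu Dhabi 2023 house fly survey: per-location L1014F genotype
# counts from PASA (RR = kdr/kdr, RS = kdr/sus, SS = sus/sus)
"location","n_RR","n_RS","n_SS"
"Mina Zayed",1,9,6
"Hadbat Al Zafranah",0,6,0
"Al Danah",0,13,6
"Al Muzoun",1,4,10
"Al Mushrif",1,3,6
"Al Bateen",0,6,9
"Al Rawdah",4,7,6
"Shahama City",0,3,15
"Al Samha",0,5,13
"Al Bahiya",1,4,3
"Baniyas",1,1,6
"Mirfa",1,4,9
"Madinat Zayed",2,7,9
"Al Hayer",1,2,6
"Al Khazna",0,4,13
"Hili",1,4,15
"Remah",0,0,8
"Central district",0,5,11
"Al Shuwaymah",0,15,12
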