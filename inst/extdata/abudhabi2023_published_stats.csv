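# Published per-location statistics of the Abu Dhabi 2023 survey,
# transcribed verbatim (pct over a fixed 32-allele denominator)
"location","pct_kdr_printed","chi2_printed","p_printed"
"Mina Zayed",34.4,0.9741,0.3236
"Hadbat Al Zafranah",18.8,6,0.0143
"Al Danah",40.6,5.1376,0.0234
"Al Muzoun",18.8,0.4166,0.5186
"Al Mushrif",15.6,0.4,0.527
"Al Bateen",18.8,0.9375,0.3329
"Al Rawdah",46.9,0.4623,0.4965
"Shahama City",9.4,0.1487,0.6997
"Al Samha",15.6,0.4682,0.4937
"Al Bahiya",18.8,0.0355,0.8504
"Baniyas",9.4,2.7823,0.0953
"Mirfa",18.8,0.3213,0.5707
"Madinat Zayed",34.4,0.1259,0.7227
"Al Hayer",12.5,1.1479,0.2839
"Al Khazna",12.5,0.3022,0.5824
"Hili",15.6,0.9304,0.3347
"Remah",0,0,NA
"Central district",15.6,0.5486,0.4588
"Al Shuwaymah",46.9,3.994,0.0456
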