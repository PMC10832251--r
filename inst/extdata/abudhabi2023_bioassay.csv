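# Abu Dhabi 2023 deltamethrin bottle bioassay; synthetic
# deterministic mortality curves reproducing each location's
# published status and time to 100% mortality at 4.5 ug/ml
"location","date","bottle_id","dose_ug_ml","n_insects","dead_0","dead_15","dead_30","dead_45","dead_60","dead_75","dead_90","dead_105","dead_120"
"Al Rawadah","10 March","Al Rawadah_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Al Rawadah","10 March","Al Rawadah_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Al Rawadah","10 March","Al Rawadah_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Al Rawadah","10 March","Al Rawadah_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Al Rawadah","10 March","Al Rawadah_C",0,25,0,0,0,0,0,0,0,0,0
"Al Mushrif","15 March","Al Mushrif_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Al Mushrif","15 March","Al Mushrif_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Al Mushrif","15 March","Al Mushrif_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Al Mushrif","15 March","Al Mushrif_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Al Mushrif","15 March","Al Mushrif_C",0,25,0,0,0,0,0,0,0,0,0
"Al Bateen","1 April","Al Bateen_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Al Bateen","1 April","Al Bateen_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Al Bateen","1 April","Al Bateen_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Al Bateen","1 April","Al Bateen_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Al Bateen","1 April","Al Bateen_C",0,25,0,0,0,0,0,0,0,0,0
"Al Wathba","1 March","Al Wathba_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Al Wathba","1 March","Al Wathba_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Al Wathba","1 March","Al Wathba_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Al Wathba","1 March","Al Wathba_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Al Wathba","1 March","Al Wathba_C",0,25,0,0,0,0,0,0,0,0,0
"Al Falah","3 March","Al Falah_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Al Falah","3 March","Al Falah_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Al Falah","3 March","Al Falah_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Al Falah","3 March","Al Falah_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Al Falah","3 March","Al Falah_C",0,25,0,0,0,0,0,0,0,0,0
"Yas Island","6 March","Yas Island_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Yas Island","6 March","Yas Island_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Yas Island","6 March","Yas Island_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Yas Island","6 March","Yas Island_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Yas Island","6 March","Yas Island_C",0,25,0,0,0,0,0,0,0,0,0
"Mussafah Shabiya","8 March","Mussafah Shabiya_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Mussafah Shabiya","8 March","Mussafah Shabiya_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Mussafah Shabiya","8 March","Mussafah Shabiya_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Mussafah Shabiya","8 March","Mussafah Shabiya_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Mussafah Shabiya","8 March","Mussafah Shabiya_C",0,25,0,0,0,0,0,0,0,0,0
"Al Adlah","10 March","Al Adlah_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Al Adlah","10 March","Al Adlah_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Al Adlah","10 March","Al Adlah_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Al Adlah","10 March","Al Adlah_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Al Adlah","10 March","Al Adlah_C",0,25,0,0,0,0,0,0,0,0,0
"Madinat Zayed","16 March","Madinat Zayed_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Madinat Zayed","16 March","Madinat Zayed_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Madinat Zayed","16 March","Madinat Zayed_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Madinat Zayed","16 March","Madinat Zayed_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Madinat Zayed","16 March","Madinat Zayed_C",0,25,0,0,0,0,0,0,0,0,0
"Bida Bint Saud","17 April","Bida Bint Saud_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Bida Bint Saud","17 April","Bida Bint Saud_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Bida Bint Saud","17 April","Bida Bint Saud_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Bida Bint Saud","17 April","Bida Bint Saud_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Bida Bint Saud","17 April","Bida Bint Saud_C",0,25,0,0,0,0,0,0,0,0,0
"Al Shwaib","28 April","Al Shwaib_T1",4.5,25,0,1,3,8,15,21,25,25,25
"Al Shwaib","28 April","Al Shwaib_T2",4.5,25,0,1,3,8,15,21,25,25,25
"Al Shwaib","28 April","Al Shwaib_T3",4.5,25,0,1,3,8,15,21,25,25,25
"Al Shwaib","28 April","Al Shwaib_T4",4.5,25,0,1,3,8,15,21,25,25,25
"Al Shwaib","28 April","Al Shwaib_C",0,25,0,0,0,0,0,0,0,0,0
"Al Saa","27 March","Al Saa_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Al Saa","27 March","Al Saa_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Al Saa","27 March","Al Saa_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Al Saa","27 March","Al Saa_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Al Saa","27 March","Al Saa_C",0,25,0,0,0,0,0,0,0,0,0
"Bu Kirayyah","1 March","Bu Kirayyah_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Bu Kirayyah","1 March","Bu Kirayyah_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Bu Kirayyah","1 March","Bu Kirayyah_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Bu Kirayyah","1 March","Bu Kirayyah_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Bu Kirayyah","1 March","Bu Kirayyah_C",0,25,0,0,0,0,0,0,0,0,0
"Malaqit","14 March","Malaqit_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Malaqit","14 March","Malaqit_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Malaqit","14 March","Malaqit_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Malaqit","14 March","Malaqit_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Malaqit","14 March","Malaqit_C",0,25,0,0,0,0,0,0,0,0,0
"Al Rawdah Al Sharqiyah","11 April","Al Rawdah Al Sharqiyah_T1",4.5,25,1,3,12,22,25,25,25,25,25
"Al Rawdah Al Sharqiyah","11 April","Al Rawdah Al Sharqiyah_T2",4.5,25,1,3,12,22,25,25,25,25,25
"Al Rawdah Al Sharqiyah","11 April","Al Rawdah Al Sharqiyah_T3",4.5,25,1,3,12,22,25,25,25,25,25
"Al Rawdah Al Sharqiyah","11 April","Al Rawdah Al Sharqiyah_T4",4.5,25,1,3,12,22,25,25,25,25,25
"Al Rawdah Al Sharqiyah","11 April","Al Rawdah Al Sharqiyah_C",0,25,0,0,0,0,0,0,0,0,0
"Al Aflaj","14 April","Al Aflaj_T1",4.5,25,0,1,3,8,15,21,25,25,25
"Al Aflaj","14 April","Al Aflaj_T2",4.5,25,0,1,3,8,15,21,25,25,25
"Al Aflaj","14 April","Al Aflaj_T3",4.5,25,0,1,3,8,15,21,25,25,25
"Al Aflaj","14 April","Al Aflaj_T4",4.5,25,0,1,3,8,15,21,25,25,25
"Al Aflaj","14 April","Al Aflaj_C",0,25,0,0,0,0,0,0,0,0,0
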