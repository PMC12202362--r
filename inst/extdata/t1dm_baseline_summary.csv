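table,variable,group,n_persons,n_eyes,mean,sd
1,age_years,control,40,70,25.00,8.249
1,age_years,NDR,51,91,23.63,9.556
1,age_years,NPDR,12,19,29.92,12.362
1,duration_years,NDR,51,91,5.479,5.427
1,duration_years,NPDR,12,19,11.458,6.747
2,age_years,control,40,70,25.00,8.249
2,age_years,lt5y,28,49,21.36,9.056
2,age_years,ge5y,23,42,26.39,9.609
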