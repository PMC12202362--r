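table,variable,group,level,count
1,sex,control,male,16
1,sex,control,female,24
1,sex,NDR,male,26
1,sex,NDR,female,25
1,sex,NPDR,male,7
1,sex,NPDR,female,5
1,laterality,control,OS,37
1,laterality,control,OD,33
1,laterality,NDR,OS,46
1,laterality,NDR,OD,45
1,laterality,NPDR,OS,10
1,laterality,NPDR,OD,9
2,sex,control,male,16
2,sex,control,female,24
2,sex,lt5y,male,15
2,sex,lt5y,female,13
2,sex,ge5y,male,11
2,sex,ge5y,female,12
2,laterality,control,OS,37
2,laterality,control,OD,33
2,laterality,lt5y,OS,25
2,laterality,lt5y,OD,24
2,laterality,ge5y,OS,21
2,laterality,ge5y,OD,21
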