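country,variable,level,prob
Wales,sex,female,0.722
Wales,sex,male,0.278
England,sex,female,0.731
England,sex,male,0.269
Wales,admission_source,hospital,0.045
Wales,admission_source,care_home,0.154
Wales,admission_source,residential_home,0.786
Wales,admission_source,other,0.016
England,admission_source,hospital,0.035
England,admission_source,care_home,0.174
England,admission_source,residential_home,0.779
England,admission_source,other,0.012
Wales,asa,1,0.027
Wales,asa,2,0.308
Wales,asa,3,0.538
Wales,asa,4,0.121
Wales,asa,5,0.006
England,asa,1,0.026
England,asa,2,0.309
England,asa,3,0.547
England,asa,4,0.114
England,asa,5,0.004
Wales,mobility,full,0.352
Wales,mobility,outdoor,0.254
Wales,mobility,indoor,0.373
Wales,mobility,none,0.020
England,mobility,full,0.358
England,mobility,outdoor,0.263
England,mobility,indoor,0.357
England,mobility,none,0.022
Wales,fracture_type,intracapsular,0.579
Wales,fracture_type,extracapsular,0.421
England,fracture_type,intracapsular,0.593
England,fracture_type,extracapsular,0.407
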