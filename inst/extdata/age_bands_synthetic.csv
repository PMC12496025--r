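country,variable,level,prob
England,age_band,60-64,0.04
England,age_band,65-69,0.06
England,age_band,70-74,0.09
England,age_band,75-79,0.15
England,age_band,80-84,0.24
England,age_band,85-89,0.24
England,age_band,90+,0.18
Wales,age_band,60-64,0.04
Wales,age_band,65-69,0.06
Wales,age_band,70-74,0.10
Wales,age_band,75-79,0.16
Wales,age_band,80-84,0.24
Wales,age_band,85-89,0.23
Wales,age_band,90+,0.17
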