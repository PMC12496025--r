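country,criterion,fy2008,fy2009,fy2010,fy2011,fy2012,fy2013,fy2014
England,bundle,0.00,0.01,0.34,0.52,0.61,0.66,0.67
England,BPT1,0.54,0.57,0.67,0.72,0.76,0.77,0.77
England,BPT2,0.01,0.05,0.74,0.88,0.94,0.97,0.98
England,BPT3,0.02,0.07,0.76,0.90,0.95,0.98,0.97
England,BPT4,0.66,0.63,0.62,0.72,0.99,1.00,1.00
England,BPT6,0.00,0.02,0.58,0.75,0.84,0.88,0.90
England,BPT7,0.02,0.08,0.88,0.92,0.94,0.96,0.97
England,BPT8,0.52,0.64,0.81,0.92,0.96,0.97,0.98
England,BPT9,0.68,0.75,0.88,0.94,0.96,0.97,0.98
Wales,bundle,0.00,0.00,0.06,0.03,0.02,0.01,0.01
Wales,BPT1,0.56,0.60,0.59,0.62,0.65,0.65,0.64
Wales,BPT2,0.00,0.03,0.17,0.15,0.19,0.15,0.22
Wales,BPT3,0.02,0.11,0.58,0.75,0.77,0.74,0.63
Wales,BPT4,0.71,0.72,0.54,0.49,0.70,0.94,0.92
Wales,BPT6,0.01,0.03,0.28,0.29,0.27,0.32,0.41
Wales,BPT7,0.03,0.20,0.76,0.88,0.87,0.84,0.89
Wales,BPT8,0.55,0.43,0.57,0.69,0.71,0.68,0.68
Wales,BPT9,0.90,0.80,0.90,0.90,0.84,0.84,0.84
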