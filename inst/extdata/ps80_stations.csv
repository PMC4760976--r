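station,date,region,ice,temp,sal,no3,si,po4
PS80/79,2012-06-30,fram_W,95,-1.69,33.75,5.67,2.74,0.58
PS80/114,2012-07-06,fram_W,99,-1.57,31.55,NA,NA,NA
PS80/117,2012-07-06,fram_W,57,-1.55,31.72,0.83,1.94,0.55
PS80/122,2012-07-07,fram_W,86,-1.46,31.33,NA,NA,NA
PS80/130,2012-07-08,fram_W,91,-1.58,32.02,NA,NA,NA
PS80/132,2012-07-09,fram_W,100,-1.49,32.48,4.10,7.56,0.64
PS80/20,2012-06-20,fram_E,0,5.25,35.07,3.58,1.88,0.30
PS80/27,2012-06-21,fram_E,0,4.37,35.11,10.12,4.38,0.71
PS80/37,2012-06-22,fram_E,0,4.82,35.11,4.14,4.04,0.39
PS80/53,2012-06-25,fram_E,8,4.98,34.96,9.44,3.97,0.71
PS80/67,2012-06-27,fram_E,59,4.10,35.03,4.04,3.71,0.42
PS80/72,2012-06-28,fram_E,79,2.80,34.51,2.61,4.15,0.42
PS80/165,2012-07-16,fram_E,0,5.02,35.01,3.24,3.72,0.39
PS80/168,2012-07-17,fram_E,0,5.91,34.94,3.18,2.46,0.37
PS80/171,2012-07-18,fram_E,0,3.04,34.56,NA,NA,NA
PS80/176,2012-07-20,fram_E,0,6.07,35.04,3.36,3.80,0.40
PS80/183,2012-07-22,fram_E,0,5.00,34.93,NA,NA,NA
PS80/184,2012-07-22,fram_E,0,6.04,35.04,10.19,5.12,0.74
PS80/185,2012-07-23,fram_E,32,4.69,34.90,0.17,3.01,0.21
PS80/209,2012-08-06,nansen,0,-0.04,34.27,5.25,2.41,0.49
PS80/213,2012-08-06,nansen,0,-1.16,33.70,0.72,1.25,0.20
PS80/215,2012-08-07,nansen,52,-1.11,33.26,0.46,0.99,0.17
PS80/218,2012-08-07,nansen,91,-1.74,34.25,5.57,1.90,0.45
PS80/220,2012-08-08,nansen,96,-1.78,34.19,4.21,1.37,0.38
PS80/230,2012-08-11,nansen,96,-1.77,34.18,NA,NA,NA
PS80/234,2012-08-12,nansen,94,-1.52,34.04,3.95,1.36,0.35
PS80/235,2012-08-13,nansen,98,-1.68,34.18,7.57,2.97,0.54
PS80/238,2012-08-14,nansen,100,-1.72,34.15,4.79,1.65,0.41
PS80/244,2012-08-16,nansen,90,-1.58,34.17,6.64,2.67,0.51
PS80/250,2012-08-18,nansen,73,-1.68,34.13,4.61,1.69,0.41
PS80/256,2012-08-20,amundsen,93,-1.68,33.74,1.13,1.23,0.22
PS80/263,2012-08-22,amundsen,94,-1.67,33.09,2.21,1.68,0.28
PS80/269,2012-08-23,amundsen,82,-1.62,33.19,2.49,2.39,0.32
PS80/271,2012-08-24,amundsen,53,-1.39,31.43,2.27,4.54,0.34
PS80/284,2012-08-26,amundsen,95,-1.55,31.18,0.59,3.62,0.24
PS80/287,2012-08-27,amundsen,10,-1.37,31.38,1.45,4.44,0.30
PS80/294,2012-08-29,amundsen,0,-1.46,32.04,1.81,4.01,0.30
PS80/311,2012-09-01,amundsen,0,-0.27,32.10,0.21,1.28,0.19
PS80/319,2012-09-02,amundsen,0,-1.46,31.84,0.45,2.75,0.22
PS80/329,2012-09-05,amundsen,49,-1.48,31.04,0.90,3.42,0.28
PS80/333,2012-09-06,amundsen,0,-1.50,31.04,1.00,4.65,0.28
PS80/336,2012-09-07,amundsen,80,-1.55,31.47,1.71,4.68,0.34
PS80/341,2012-09-09,amundsen,66,-1.54,29.97,0.54,4.69,0.25
PS80/357,2012-09-19,amundsen,100,-1.80,33.11,1.00,1.52,0.23
PS80/370,2012-09-23,amundsen,100,-1.79,32.93,1.68,2.23,0.28
PS80/396,2012-09-29,amundsen,100,-1.79,32.78,2.18,1.15,0.28
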