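metric,region_type,region,n,mean,sd,reference,difference,ci_low,ci_high,p
FA,global,global,10,0.613,0.044,NA,NA,NA,NA,NA
FA,slice,mid,10,0.623,0.043,TRUE,NA,NA,NA,NA
FA,slice,apical,10,0.608,0.050,FALSE,-0.015,-0.040,0.010,0.25
FA,slice,basal,10,0.608,0.046,FALSE,-0.015,-0.040,0.010,0.25
FA,wall,lateral,10,0.614,0.041,TRUE,NA,NA,NA,NA
FA,wall,anterior,10,0.615,0.039,FALSE,0.002,-0.021,0.024,0.90
FA,wall,inferior,10,0.611,0.040,FALSE,-0.003,-0.026,0.019,0.79
FA,wall,septal,10,0.610,0.059,FALSE,-0.003,-0.026,0.019,0.77
MD,global,global,10,0.750,0.154,NA,NA,NA,NA,NA
MD,slice,mid,10,0.742,0.178,TRUE,NA,NA,NA,NA
MD,slice,apical,10,0.785,0.152,FALSE,0.042,-0.017,0.101,0.16
MD,slice,basal,10,0.726,0.145,FALSE,-0.016,-0.075,0.043,0.60
MD,wall,lateral,10,0.714,0.155,TRUE,NA,NA,NA,NA
MD,wall,anterior,10,0.758,0.145,FALSE,0.044,0.004,0.083,0.029
MD,wall,inferior,10,0.742,0.137,FALSE,0.028,-0.011,0.067,0.16
MD,wall,septal,10,0.784,0.188,FALSE,0.070,0.031,0.109,0.001
HA,layer,endocardial,10,38.9,8.1,NA,NA,NA,NA,NA
HA,layer,mesocardial,10,3.5,6.9,NA,NA,NA,NA,NA
HA,layer,epicardial,10,-34.3,7.6,NA,NA,NA,NA,NA
HA,layer_slice,endocardial/mid,10,40.0,4.6,TRUE,NA,NA,NA,NA
HA,layer_slice,endocardial/apical,10,41.0,7.2,FALSE,1.0,-2.6,4.7,0.58
HA,layer_slice,endocardial/basal,10,36.3,6.0,FALSE,-3.7,-7.4,-0.1,0.044
HA,layer_slice,mesocardial/mid,10,3.0,3.2,TRUE,NA,NA,NA,NA
HA,layer_slice,mesocardial/apical,10,4.3,5.3,FALSE,1.3,-1.5,4.0,0.37
HA,layer_slice,mesocardial/basal,10,3.5,4.3,FALSE,0.5,-2.2,3.2,0.72
HA,layer_slice,epicardial/mid,10,-34.4,3.2,TRUE,NA,NA,NA,NA
HA,layer_slice,epicardial/apical,10,-33.8,6.5,FALSE,0.6,-3.0,4.2,0.73
HA,layer_slice,epicardial/basal,10,-34.8,4.1,FALSE,-0.4,-4.0,3.2,0.82
HA,layer_wall,endocardial/lateral,10,42.6,5.5,TRUE,NA,NA,NA,NA
HA,layer_wall,endocardial/anterior,10,45.1,6.6,FALSE,2.5,-1.6,6.7,0.24
HA,layer_wall,endocardial/inferior,10,33.9,8.4,FALSE,-8.7,-12.8,-4.5,0.001
HA,layer_wall,endocardial/septal,10,34.1,5.2,FALSE,-8.5,-12.6,-4.3,0.001
HA,layer_wall,mesocardial/lateral,10,7.6,4.5,TRUE,NA,NA,NA,NA
HA,layer_wall,mesocardial/anterior,10,7.3,6.1,FALSE,-0.4,-4.6,3.9,0.87
HA,layer_wall,mesocardial/inferior,10,-0.2,5.7,FALSE,-7.8,-12.1,-3.5,0.001
HA,layer_wall,mesocardial/septal,10,-0.7,6.9,FALSE,-8.3,-12.6,-4.0,0.001
HA,layer_wall,epicardial/lateral,10,-28.7,6.0,TRUE,NA,NA,NA,NA
HA,layer_wall,epicardial/anterior,10,-36.9,6.9,FALSE,-8.3,-13.8,-2.7,0.004
HA,layer_wall,epicardial/inferior,10,-32.4,5.4,FALSE,-3.7,-9.3,1.8,0.19
HA,layer_wall,epicardial/septal,10,-39.1,8.2,FALSE,-10.4,-16.0,-4.9,0.001
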