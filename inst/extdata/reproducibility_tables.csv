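metric,region_type,region,n,mean_value,mean_diff,sd_diff,loa_low,loa_high,cov_pct
FA,global,global,10,0.617,-0.008,0.045,-0.096,0.079,7.2
FA,slice,apical,10,0.614,-0.013,0.054,-0.119,0.093,8.8
FA,slice,mid,10,0.622,0.001,0.051,-0.099,0.102,8.2
FA,slice,basal,10,0.614,-0.013,0.043,-0.098,0.072,7.1
FA,wall,anterior,10,0.620,-0.009,0.042,-0.091,0.073,6.8
FA,wall,lateral,10,0.608,0.012,0.059,-0.104,0.128,9.7
FA,wall,inferior,10,0.620,-0.018,0.053,-0.123,0.087,8.6
FA,wall,septal,10,0.619,-0.017,0.053,-0.121,0.086,8.5
MD,global,global,10,0.728,0.045,0.135,-0.220,0.310,18.6
MD,slice,apical,10,0.764,0.041,0.176,-0.304,0.385,23.0
MD,slice,mid,10,0.720,0.045,0.160,-0.268,0.358,22.2
MD,slice,basal,10,0.704,0.045,0.115,-0.181,0.271,16.4
MD,wall,anterior,10,0.727,0.061,0.112,-0.158,0.281,15.4
MD,wall,lateral,10,0.713,0.003,0.164,-0.317,0.324,22.9
MD,wall,inferior,10,0.716,0.053,0.140,-0.221,0.327,19.5
MD,wall,septal,10,0.751,0.067,0.232,-0.388,0.521,30.9
HA,layer,endocardial,10,38.4,1.2,4.8,-8.3,10.6,NA
HA,layer,mesocardial,10,3.9,-0.6,3.4,-7.3,6.0,NA
HA,layer,epicardial,10,-33.1,-2.7,2.9,-8.4,3.0,NA
HA,layer_slice,endocardial/apical,10,39.5,3.0,10.6,-17.8,23.9,NA
HA,layer_slice,mesocardial/apical,10,4.3,0.0,6.1,-12.0,12.0,NA
HA,layer_slice,epicardial/apical,10,-32.0,-3.6,6.4,-16.2,8.9,NA
HA,layer_slice,endocardial/mid,10,39.1,1.9,6.2,-10.3,14.1,NA
HA,layer_slice,mesocardial/mid,10,3.4,-0.7,4.7,-9.9,8.4,NA
HA,layer_slice,epicardial/mid,10,-33.0,-2.9,6.8,-16.2,10.4,NA
HA,layer_slice,endocardial/basal,10,36.6,-0.8,4.4,-9.3,7.8,NA
HA,layer_slice,mesocardial/basal,10,4.1,-1.1,3.2,-7.3,5.2,NA
HA,layer_slice,epicardial/basal,10,-33.9,-1.8,4.7,-11.0,7.4,NA
HA,layer_wall,endocardial/anterior,10,43.2,3.7,8.6,-13.2,20.5,NA
HA,layer_wall,mesocardial/anterior,10,6.0,2.6,5.5,-8.1,13.3,NA
HA,layer_wall,epicardial/anterior,10,-36.5,-0.9,7.3,-15.2,13.5,NA
HA,layer_wall,endocardial/lateral,10,42.6,0.0,4.9,-9.7,9.7,NA
HA,layer_wall,mesocardial/lateral,10,8.7,-2.2,6.9,-15.8,11.4,NA
HA,layer_wall,epicardial/lateral,10,-27.7,-2.0,7.8,-17.4,13.3,NA
HA,layer_wall,endocardial/inferior,10,34.2,-0.6,6.7,-13.6,12.5,NA
HA,layer_wall,mesocardial/inferior,10,0.7,-1.7,7.2,-15.9,12.4,NA
HA,layer_wall,epicardial/inferior,10,-30.8,-3.2,9.4,-21.7,15.3,NA
HA,layer_wall,endocardial/septal,10,33.3,1.6,8.0,-14.1,17.4,NA
HA,layer_wall,mesocardial/septal,10,0.2,-1.8,6.8,-15.1,11.6,NA
HA,layer_wall,epicardial/septal,10,-36.7,-4.9,7.3,-19.3,9.5,NA
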