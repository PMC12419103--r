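phase,artery,side,icc,icc_ci_low,icc_ci_high,mean_sim,sd_sim,mean_meas,sd_meas,mean_diff_cms,pct_diff
PSV,MCA,right,0.755,0.575,0.859,98.6,25,96.8,30,-1.8,-1.8
PSV,MCA,left,0.695,0.471,0.824,96.3,25.8,93.7,26.6,-2.6,-2.7
PSV,ACA,right,0.686,0.448,0.821,78.8,26.6,77.4,18.2,-1.4,-1.8
PSV,ACA,left,0.703,0.484,0.829,76.0,27.3,77.3,20.4,1.3,1.7
PSV,PCA,right,0.661,0.415,0.805,55.5,17.7,58.8,14.2,3.3,5.9
PSV,PCA,left,0.769,0.592,0.869,58.2,23.9,57.3,16.1,-0.9,-1.5
PSV,BA,NA,0.827,0.579,0.916,57.8,19.1,50.2,16.7,-7.6,-13.1
PSV,V4,right,0.876,0.757,0.924,51.3,17.4,46.7,16.9,-4.6,-9.0
PSV,V4,left,0.758,0.369,0.888,51.4,17.3,42.2,15.9,-9.2,-17.9
EDV,MCA,right,0.822,0.690,0.897,37.2,12.6,37.5,14.1,0.25,0.7
EDV,MCA,left,0.820,0.686,0.897,36.4,12.5,37.0,13.6,0.6,1.6
EDV,ACA,right,0.811,0.671,0.892,27.7,11.3,29.0,9.2,1.4,5
EDV,ACA,left,0.712,0.502,0.834,26.9,12.0,29.6,9.7,2.7,10
EDV,PCA,right,0.793,0.584,0.890,21.1,8.7,24.4,8.0,3.2,15
EDV,PCA,left,0.729,0.525,0.846,20.0,10.1,22.3,7.9,2.3,11.5
EDV,BA,NA,0.915,0.832,0.954,21.0,10.0,18.9,8.6,-2.1,-10
EDV,V4,right,0.896,0.817,0.941,18.8,8.8,17.5,7.9,-1.3,-6.9
EDV,V4,left,0.877,0.716,0.939,19.9,9.0,17.0,8.1,-2.9,-14.5
MFV,MCA,right,0.651,0.392,0.799,33.5,9.5,33.4,10.7,-0.07,-0.2
MFV,MCA,left,0.726,0.524,0.842,33.6,9.7,34.1,11.2,0.5,1.4
MFV,ACA,right,0.761,0.580,0.864,26.2,10.1,27.5,7.9,1.4,5.3
MFV,ACA,left,0.622,0.329,0.787,23.8,10.0,27.5,8.5,3.8,9.7
MFV,PCA,right,0.652,0.397,0.800,20.3,8.0,22.2,6.3,1.9,9
MFV,PCA,left,0.676,0.433,0.816,20.2,8.2,21.5,6.6,1.3,6.4
MFV,BA,NA,0.856,0.687,0.927,20.3,8.6,17.5,7.2,-2.7,-13
MFV,V4,right,0.771,0.480,0.887,17.5,8.0,14.2,5.8,-3.3,-19
MFV,V4,left,0.724,0.065,0.889,18.6,7.7,13.4,6.4,-5.2,-29
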