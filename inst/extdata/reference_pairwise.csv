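variable,group_i,group_j,mean_difference,std_error,significance
mmse,1,2,-6.915,0.707,<0.001
mmse,1,3,-8.568,0.733,<0.001
mmse,2,1,6.915,0.707,<0.001
mmse,2,3,-1.654,0.359,<0.001
mmse,3,1,8.568,0.733,<0.001
mmse,3,2,1.654,0.359,<0.001
moca,1,2,-7.358,1.150,<0.001
moca,1,3,-11.523,1.191,<0.001
moca,2,1,7.358,1.150,<0.001
moca,2,3,-4.165,0.583,<0.001
moca,3,1,11.523,1.191,<0.001
moca,3,2,4.165,0.583,<0.001
tmt_a,1,2,52.437,15.016,<0.001
tmt_a,1,3,84.068,15.555,<0.001
tmt_a,2,1,-52.437,15.016,<0.001
tmt_a,2,3,31.631,7.613,<0.001
tmt_a,3,1,-84.068,15.555,<0.001
tmt_a,3,2,-31.631,7.613,<0.001
tmt_b,1,2,95.899,25.716,<0.001
tmt_b,1,3,171.705,26.640,<0.001
tmt_b,2,1,-95.899,25.716,<0.001
tmt_b,2,3,75.806,13.038,<0.001
tmt_b,3,1,-171.705,26.640,<0.001
tmt_b,3,2,-75.806,13.038,<0.001
stroop,1,2,22.875,13.948,0.103
stroop,1,3,63.807,14.449,<0.001
stroop,2,1,-22.875,13.948,0.103
stroop,2,3,40.932,7.072,<0.001
stroop,3,1,-63.807,14.449,<0.001
stroop,3,2,-40.932,7.072,<0.001
vft,1,2,-4.122,1.424,0.004
vft,1,3,-7.330,1.475,<0.001
vft,2,1,4.122,1.424,0.004
vft,2,3,-3.208,0.722,<0.001
vft,3,1,7.330,1.475,<0.001
vft,3,2,3.208,0.722,<0.001
avlt4,1,2,-2.098,0.764,0.007
avlt4,1,3,-5.023,0.792,<0.001
avlt4,2,1,2.098,0.764,0.007
avlt4,2,3,-2.925,0.388,<0.001
avlt4,3,1,5.023,0.792,<0.001
avlt4,3,2,2.925,0.388,<0.001
avlt5,1,2,-2.223,0.790,0.006
avlt5,1,3,-5.852,0.819,<0.001
avlt5,2,1,2.223,0.790,0.006
avlt5,2,3,-3.629,0.401,<0.001
avlt5,3,1,5.852,0.819,<0.001
avlt5,3,2,3.629,0.401,<0.001
rey_o,1,2,-8.411,1.528,<0.001
rey_o,1,3,-9.841,1.583,<0.001
rey_o,2,1,8.411,1.528,<0.001
rey_o,2,3,-1.430,0.775,0.067
rey_o,3,1,9.841,1.583,<0.001
rey_o,3,2,1.430,0.775,<0.001
bnt,1,2,-5.032,1.313,<0.001
bnt,1,3,-7.886,1.361,<0.001
bnt,2,1,5.032,1.313,<0.001
bnt,2,3,-2.855,0.666,<0.001
bnt,3,1,7.886,1.361,<0.001
bnt,3,2,2.855,0.666,<0.001
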