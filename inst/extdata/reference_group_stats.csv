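variable,group,n,mean,sd
age,1,44,75.875,5.988
age,2,82,67.127,7.205
age,3,8,65.75,7.574
education,1,44,8.5,4.242
education,2,82,10.178,7.205
education,3,8,11.636,2.805
mmse,1,44,20.25,3.767
mmse,2,82,27.165,1.945
mmse,3,8,28.818,1.093
moca,1,44,14.25,2.817
moca,2,82,21.608,3.328
moca,3,8,25.773,2.575
tmt_a,1,44,145.5,56.622
tmt_a,2,82,93.063,44.844
tmt_a,3,8,61.432,23.903
tmt_b,1,44,319,72.856
tmt_b,2,82,223.101,80.342
tmt_b,3,8,147.296,37.690
stroop,1,44,143.875,38.908
stroop,2,82,121,44.727
stroop,3,8,80.068,15.623
vft,1,44,9.625,1.867
vft,2,82,13.747,4.211
vft,3,8,16.955,3.219
avlt4,1,44,1.75,1.561
avlt4,2,82,3.848,2.129
avlt4,3,8,6.773,1.941
avlt5,1,44,0.625,0.857
avlt5,2,82,2.848,2.159
avlt5,3,8,6.477,2.169
rey_o,1,44,24.5,5.523
rey_o,2,82,32.911,4.032
rey_o,3,8,34.341,3.819
bnt,1,44,17.5,4.770
bnt,2,82,22.532,3.697
bnt,3,8,25.386,2.90
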