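cohort,block,original,nnunet,nnunet_resnet,ours
dementia,1,32228.34,9177.14,9841,25220.8
dementia,2,35938.2,16366.52,15916.5,16971.6
dementia,3,28224.04,11185.32,8970.92,10676.4
dementia,4,21992.88,6540.36,16049.1,16156.7
MCI,1,14867.6,6658,794.8,13279.2
MCI,2,13169.44,9196.8,1454,9996.8
MCI,3,13735.94,12865.38,631.2,11361.6
MCI,4,13245.4,8655.92,1548.4,9443.4
NCI,1,2912.68,1897.22,9406.4,2237.6
NCI,2,3828.44,1896.44,14586.96,2630.4
NCI,3,2900,1411.98,16260.84,1785.8
NCI,4,3314.28,1480.8,8918.76,2188
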