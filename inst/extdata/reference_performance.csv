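cohort,endpoint,vertebra,threshold,auc,sensitivity,specificity,accuracy,n_pos,n_neg
experimental,osteoporosis,L1,0.121,0.928,95.7,78.0,81.9,23,82
experimental,osteoporosis,L2,0.103,0.921,87.0,81.7,82.9,23,82
experimental,osteoporosis,L3,0.107,0.937,87.0,76.8,79.0,23,82
experimental,osteoporosis,L4,0.114,0.924,95.7,75.6,80.0,23,82
experimental,osteoporosis,average,0.116,0.930,95.7,75.6,80.0,23,82
experimental,osteopenia,L1,0.134,0.883,81.3,84.2,82.9,48,57
experimental,osteopenia,L2,0.125,0.901,83.3,82.5,84.6,48,57
experimental,osteopenia,L3,0.129,0.889,83.3,75.4,79.8,48,57
experimental,osteopenia,L4,0.141,0.884,89.6,73.7,81.7,48,57
experimental,osteopenia,average,0.126,0.897,81.3,82.5,82.7,48,57
test,osteoporosis,L1,0.121,NA,100.0,75.4,80.0,14,61
test,osteoporosis,L2,0.103,NA,85.7,83.6,84.0,14,61
test,osteoporosis,L3,0.107,NA,100.0,72.1,77.3,14,61
test,osteoporosis,L4,0.114,NA,85.7,75.4,77.3,14,61
test,osteoporosis,average,0.116,NA,100.0,73.8,78.7,14,61
test,osteopenia,L1,0.134,NA,84.4,83.7,84.0,32,43
test,osteopenia,L2,0.125,NA,81.3,83.7,82.7,32,43
test,osteopenia,L3,0.129,NA,81.3,79.1,80.0,32,43
test,osteopenia,L4,0.141,NA,87.5,72.1,78.7,32,43
test,osteopenia,average,0.126,NA,81.3,83.7,82.7,32,43
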