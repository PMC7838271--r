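"fluorophore","kind","wavelength_nm","intensity"
"mAzure","ex",395,0.01111
"mAzure","ex",400,0.02279
"mAzure","ex",405,0.04394
"mAzure","ex",410,0.07956
"mAzure","ex",415,0.13534
"mAzure","ex",420,0.21627
"mAzure","ex",425,0.32465
"mAzure","ex",430,0.45783
"mAzure","ex",435,0.60653
"mAzure","ex",440,0.75484
"mAzure","ex",445,0.8825
"mAzure","ex",450,0.96923
"mAzure","ex",455,1
"mAzure","ex",460,0.96923
"mAzure","ex",465,0.8825
"mAzure","ex",470,0.75484
"mAzure","ex",475,0.60653
"mAzure","ex",480,0.45783
"mAzure","ex",485,0.32465
"mAzure","ex",490,0.21627
"mAzure","ex",495,0.13534
"mAzure","ex",500,0.07956
"mAzure","ex",505,0.04394
"mAzure","ex",510,0.02279
"mAzure","ex",515,0.01111
"mAzure","em",435,0.02426
"mAzure","em",440,0.04394
"mAzure","em",445,0.07557
"mAzure","em",450,0.12345
"mAzure","em",455,0.1915
"mAzure","em",460,0.2821
"mAzure","em",465,0.39465
"mAzure","em",470,0.52432
"mAzure","em",475,0.66151
"mAzure","em",480,0.7926
"mAzure","em",485,0.90185
"mAzure","em",490,0.9745
"mAzure","em",495,1
"mAzure","em",500,0.9745
"mAzure","em",505,0.90185
"mAzure","em",510,0.7926
"mAzure","em",515,0.66151
"mAzure","em",520,0.52432
"mAzure","em",525,0.39465
"mAzure","em",530,0.2821
"mAzure","em",535,0.1915
"mAzure","em",540,0.12345
"mAzure","em",545,0.07557
"mAzure","em",550,0.04394
"mAzure","em",555,0.02426
"mJade","ex",440,0.00387
"mJade","ex",445,0.00939
"mJade","ex",450,0.02111
"mJade","ex",455,0.04394
"mJade","ex",460,0.08466
"mJade","ex",465,0.15101
"mJade","ex",470,0.24935
"mJade","ex",475,0.38117
"mJade","ex",480,0.53941
"mJade","ex",485,0.70665
"mJade","ex",490,0.857
"mJade","ex",495,0.96215
"mJade","ex",500,1
"mJade","ex",505,0.96215
"mJade","ex",510,0.857
"mJade","ex",515,0.70665
"mJade","ex",520,0.53941
"mJade","ex",525,0.38117
"mJade","ex",530,0.24935
"mJade","ex",535,0.15101
"mJade","ex",540,0.08466
"mJade","ex",545,0.04394
"mJade","ex",550,0.02111
"mJade","ex",555,0.00939
"mJade","ex",560,0.00387
"mJade","em",470,0.01111
"mJade","em",475,0.02279
"mJade","em",480,0.04394
"mJade","em",485,0.07956
"mJade","em",490,0.13534
"mJade","em",495,0.21627
"mJade","em",500,0.32465
"mJade","em",505,0.45783
"mJade","em",510,0.60653
"mJade","em",515,0.75484
"mJade","em",520,0.8825
"mJade","em",525,0.96923
"mJade","em",530,1
"mJade","em",535,0.96923
"mJade","em",540,0.8825
"mJade","em",545,0.75484
"mJade","em",550,0.60653
"mJade","em",555,0.45783
"mJade","em",560,0.32465
"mJade","em",565,0.21627
"mJade","em",570,0.13534
"mJade","em",575,0.07956
"mJade","em",580,0.04394
"mJade","em",585,0.02279
"mJade","em",590,0.01111
"mGarnet","ex",500,0.02426
"mGarnet","ex",505,0.04394
"mGarnet","ex",510,0.07557
"mGarnet","ex",515,0.12345
"mGarnet","ex",520,0.1915
"mGarnet","ex",525,0.2821
"mGarnet","ex",530,0.39465
"mGarnet","ex",535,0.52432
"mGarnet","ex",540,0.66151
"mGarnet","ex",545,0.7926
"mGarnet","ex",550,0.90185
"mGarnet","ex",555,0.9745
"mGarnet","ex",560,1
"mGarnet","ex",565,0.9745
"mGarnet","ex",570,0.90185
"mGarnet","ex",575,0.7926
"mGarnet","ex",580,0.66151
"mGarnet","ex",585,0.52432
"mGarnet","ex",590,0.39465
"mGarnet","ex",595,0.2821
"mGarnet","ex",600,0.1915
"mGarnet","ex",605,0.12345
"mGarnet","ex",610,0.07557
"mGarnet","ex",615,0.04394
"mGarnet","ex",620,0.02426
"mGarnet","em",540,0.05613
"mGarnet","em",545,0.08892
"mGarnet","em",550,0.13534
"mGarnet","em",555,0.1979
"mGarnet","em",560,0.27804
"mGarnet","em",565,0.37531
"mGarnet","em",570,0.48675
"mGarnet","em",575,0.60653
"mGarnet","em",580,0.72615
"mGarnet","em",585,0.83527
"mGarnet","em",590,0.92312
"mGarnet","em",595,0.9802
"mGarnet","em",600,1
"mGarnet","em",605,0.9802
"mGarnet","em",610,0.92312
"mGarnet","em",615,0.83527
"mGarnet","em",620,0.72615
"mGarnet","em",625,0.60653
"mGarnet","em",630,0.48675
"mGarnet","em",635,0.37531
"mGarnet","em",640,0.27804
"mGarnet","em",645,0.1979
"mGarnet","em",650,0.13534
"mGarnet","em",655,0.08892
"mGarnet","em",660,0.05613
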