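i,j,relation,posterior
R001,R002,half_sib,0.97
R003,R004,half_sib,0.97
R005,R006,half_sib,0.97
R007,R008,half_sib,0.98
R009,R010,half_sib,0.98
R011,R012,half_sib,0.99
R013,R014,half_sib,0.96
R015,R016,half_sib,0.95
R017,R018,half_sib,0.96
R019,R020,half_sib,0.95
R021,R022,half_sib,0.98
R023,R024,half_sib,0.99
R025,R026,half_sib,0.98
R027,R028,half_sib,0.99
R029,R030,half_sib,0.98
R031,R032,half_sib,0.96
R033,R034,half_sib,0.98
R035,R036,half_sib,0.98
R037,R038,full_sib,1
R039,R040,full_sib,1
R041,R042,half_sib,0.82
R042,R043,half_sib,0.93
R044,R045,half_sib,0.85
R045,R046,half_sib,0.86
R047,R048,half_sib,0.76
R048,R049,half_sib,0.79
R050,R051,half_sib,0.93
R051,R052,half_sib,0.78
R053,R054,half_sib,0.8
R054,R055,half_sib,0.87
R056,R057,half_sib,0.85
R057,R058,half_sib,0.84
R059,R060,half_sib,0.81
R060,R061,half_sib,0.91
R062,R063,half_sib,0.91
R063,R064,half_sib,0.88
R065,R066,half_sib,0.86
R066,R067,half_sib,0.79
R068,R069,half_sib,0.93
R069,R070,half_sib,0.81
R071,R072,full_sib,1
R072,R073,half_sib,0.89
R073,R074,half_sib,0.83
R075,R076,half_sib,0.88
R076,R077,half_sib,0.81
R077,R078,half_sib,0.86
R078,R079,half_sib,0.79
R075,R077,half_sib,0.77
R133,R168,half_sib,0.75
R126,R157,half_sib,0.75
R128,R136,half_sib,0.34
R100,R140,half_sib,0.24
R098,R115,half_sib,0.59
R105,R168,half_sib,0.67
R131,R139,half_sib,0.61
R088,R141,half_sib,0.22
R085,R147,half_sib,0.46
R139,R145,half_sib,0.72
R083,R107,half_sib,0.67
R155,R164,half_sib,0.26
R098,R141,half_sib,0.41
R108,R134,half_sib,0.55
R145,R155,half_sib,0.25
R085,R103,half_sib,0.71
R162,R164,half_sib,0.39
R095,R125,half_sib,0.69
R103,R105,half_sib,0.57
R083,R140,half_sib,0.22
R101,R150,half_sib,0.47
R106,R158,half_sib,0.64
R110,R136,half_sib,0.63
R110,R141,half_sib,0.37
R097,R098,half_sib,0.69
R084,R118,half_sib,0.23
R111,R127,half_sib,0.37
R090,R152,half_sib,0.73
R080,R121,half_sib,0.65
R115,R143,half_sib,0.73
R080,R128,half_sib,0.6
R080,R088,half_sib,0.66
R095,R152,half_sib,0.6
R099,R121,half_sib,0.53
R111,R165,half_sib,0.41
R108,R133,half_sib,0.28
R116,R161,half_sib,0.34
R111,R137,half_sib,0.38
R099,R102,half_sib,0.41
R120,R136,half_sib,0.23
R080,R132,half_sib,0.71
R091,R166,half_sib,0.25
R109,R148,half_sib,0.53
R080,R083,half_sib,0.37
R122,R150,half_sib,0.35
R124,R162,half_sib,0.37
R094,R160,half_sib,0.61
R105,R109,half_sib,0.32
R109,R146,half_sib,0.36
R133,R136,half_sib,0.7
R110,R135,half_sib,0.34
R103,R148,half_sib,0.65
R096,R138,half_sib,0.58
R152,R165,half_sib,0.25
R105,R167,half_sib,0.71
R133,R155,half_sib,0.43
R083,R084,half_sib,0.71
R117,R121,half_sib,0.21
R092,R143,half_sib,0.24
R085,R111,half_sib,0.2
R110,R162,half_sib,0.26
R088,R156,half_sib,0.36
R125,R131,half_sib,0.48
R091,R130,half_sib,0.2
R097,R130,half_sib,0.32
R114,R122,half_sib,0.22
R090,R092,half_sib,0.53
R099,R112,half_sib,0.49
R095,R128,half_sib,0.33
R083,R110,half_sib,0.63
R106,R145,half_sib,0.65
R136,R153,half_sib,0.41
R098,R144,half_sib,0.24
R100,R134,half_sib,0.5
R104,R163,half_sib,0.55
R093,R156,half_sib,0.59
R111,R126,half_sib,0.2
R089,R106,half_sib,0.55
R129,R140,half_sib,0.54
R127,R166,half_sib,0.62
R112,R141,half_sib,0.55
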