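patient_id,age,gender,max_nodule_size,multifocality,ETE,TLNR,LLNR,TLNN,LLNN,surgery,HT,event,time
SYN001,12,female,1.5,0,1,0.5833,0,7,0,lobectomy,1,1,26
SYN002,17,female,2.2,1,0,0.2667,0.2667,4,4,lobectomy,0,0,121
SYN003,15,female,1.8,0,0,0.2727,0.2727,3,3,lobectomy,1,0,108
SYN004,15,female,3,0,1,0,0,0,0,total,0,0,24
SYN005,15,female,1.5,0,0,0,0,0,0,lobectomy,0,0,149
SYN006,18,female,1.8,0,1,0.7143,0.2857,10,4,total,1,1,81
SYN007,16,male,0.9,0,0,0,0,0,0,lobectomy,0,0,55
SYN008,13,female,3.1,0,0,0.5,0,8,0,lobectomy,0,0,18
SYN009,17,female,4.1,0,0,0,0,0,0,total,0,0,35
SYN010,8,female,3.5,0,1,0.3846,0.1538,5,2,lobectomy,0,0,96
SYN011,16,male,5.8,1,1,0,0,0,0,total,1,0,62
SYN012,16,female,0.7,0,0,0.5,0,5,0,total,0,0,87
SYN013,16,female,0.5,0,0,0.2308,0.2308,3,3,lobectomy,0,0,71
SYN014,16,female,1.9,1,0,0.6,0.4,9,6,total,1,0,47
SYN015,17,female,0.5,0,0,0.3333,0,5,0,lobectomy,0,0,129
SYN016,10,female,0.9,0,0,0.5833,0.5833,7,7,lobectomy,0,0,83
SYN017,17,female,3.6,1,0,0.2308,0.2308,3,3,lobectomy,0,0,131
SYN018,9,female,3,0,0,0.25,0.25,2,2,lobectomy,0,0,71
SYN019,14,female,1.8,1,0,0.4,0.2,6,3,lobectomy,0,0,133
SYN020,17,female,1.8,0,0,0.4375,0.25,7,4,lobectomy,0,0,52
SYN021,15,female,3.3,1,1,0.3333,0.3333,3,3,lobectomy,1,0,43
SYN022,14,female,3.3,0,1,0.4444,0.1111,8,2,total,0,1,14
SYN023,17,female,3.4,0,0,0.4,0,8,0,total,0,0,80
SYN024,17,male,3.4,0,0,0.5455,0,6,0,lobectomy,0,0,14
SYN025,13,female,1.5,0,1,0.5455,0.5455,6,6,lobectomy,0,1,41
SYN026,13,female,0.5,0,0,0.5385,0.1538,7,2,total,0,1,33
SYN027,14,female,2.8,0,0,0,0,0,0,total,0,0,71
SYN028,16,male,1.1,0,0,0,0,0,0,lobectomy,1,0,16
SYN029,17,female,2.7,0,0,0,0,0,0,total,0,0,94
SYN030,16,female,2.2,0,0,0.4615,0.3077,6,4,total,0,0,103
SYN031,17,female,2.6,0,1,0.3333,0.3333,2,2,lobectomy,0,0,60
SYN032,18,male,2.4,0,0,0.4615,0.4615,6,6,lobectomy,1,0,39
SYN033,17,female,3.5,0,1,0.5625,0,9,0,lobectomy,0,0,57
SYN034,17,female,0.5,1,0,0.5556,0.3333,5,3,total,0,0,48
SYN035,18,female,3.3,0,1,0,0,0,0,total,0,0,119
SYN036,16,male,2.4,0,0,0.4286,0,6,0,total,0,0,115
SYN037,15,female,2.7,0,0,0.2,0,3,0,lobectomy,0,0,101
SYN038,15,female,2.7,0,0,0,0,0,0,total,0,0,125
SYN039,13,female,4.2,0,0,0.4706,0,8,0,lobectomy,0,0,56
SYN040,11,female,1.9,0,1,0.4286,0,6,0,lobectomy,0,0,29
SYN041,17,male,1.6,1,0,0.3846,0.1538,5,2,total,0,0,106
SYN042,16,male,3.4,0,0,0.6667,0,6,0,lobectomy,0,0,139
SYN043,16,male,0.5,0,0,0.25,0,2,0,lobectomy,0,0,33
SYN044,14,female,3.4,0,0,0.5,0,9,0,total,1,1,9
SYN045,18,male,3,0,0,0.3571,0,5,0,lobectomy,0,0,45
SYN046,17,male,2.7,0,0,0.5,0.25,4,2,lobectomy,0,0,89
SYN047,18,female,1.8,0,1,0.2667,0.2667,4,4,total,0,0,143
SYN048,15,male,3.3,0,0,0.4,0.2,4,2,lobectomy,0,0,137
SYN049,17,male,0.5,1,0,0,0,0,0,lobectomy,0,0,71
SYN050,17,female,1.7,0,1,0.3846,0,5,0,total,0,0,147
SYN051,18,male,4.1,0,1,0.6154,0.1923,16,5,lobectomy,0,0,31
SYN052,11,female,2.5,0,0,0,0,0,0,lobectomy,0,0,25
SYN053,14,female,2.2,0,0,0.5,0,8,0,total,0,1,21
SYN054,15,female,1.3,0,1,0.5333,0.2,8,3,total,0,0,27
SYN055,16,male,4.1,0,0,0,0,0,0,total,0,0,99
SYN056,16,female,2.4,0,0,0.5455,0.3636,6,4,total,0,0,135
SYN057,16,male,3.1,1,0,0.5,0,4,0,total,0,0,66
SYN058,18,female,2,1,0,0.4615,0,6,0,total,0,0,41
SYN059,17,male,1,0,0,0.4,0.3,4,3,lobectomy,0,0,63
SYN060,16,male,2.7,1,0,0.4286,0.1429,9,3,lobectomy,1,1,104
SYN061,18,male,3.1,0,1,0.6364,0,7,0,lobectomy,0,0,53
SYN062,16,female,0.9,1,0,0.4167,0,5,0,lobectomy,0,0,51
SYN063,12,female,4.4,0,0,0.25,0.125,4,2,lobectomy,1,0,76
SYN064,16,female,4.7,1,1,0.375,0.125,6,2,lobectomy,1,0,71
SYN065,17,female,2.8,0,0,0,0,0,0,lobectomy,0,0,61
SYN066,16,female,1.3,0,1,0.4737,0.1579,9,3,total,0,0,112
SYN067,15,female,1.6,1,0,0.4,0,6,0,total,1,1,47
SYN068,17,male,2.5,0,0,0.4615,0,6,0,total,0,0,78
SYN069,18,female,0.5,0,0,0.4,0,6,0,lobectomy,0,0,20
SYN070,16,female,2.9,0,0,0.5,0.4,5,4,lobectomy,1,0,145
SYN071,14,female,3.3,0,0,0.4615,0.3077,6,4,total,0,0,85
SYN072,18,male,1.3,1,0,0.375,0.375,6,6,lobectomy,0,0,110
SYN073,16,female,0.5,0,0,0.3,0.3,3,3,lobectomy,0,0,123
SYN074,18,female,1.7,0,0,0.4286,0.1905,9,4,total,0,0,58
SYN075,16,female,3.1,0,0,0.4286,0.0476,9,1,total,0,1,116
SYN076,18,female,1.3,0,0,0.4375,0.375,7,6,total,1,0,117
SYN077,18,female,4.2,0,0,0.5833,0.25,7,3,lobectomy,0,0,92
SYN078,16,female,4.7,0,0,0,0,0,0,lobectomy,0,0,141
SYN079,16,female,0.5,0,0,0.3571,0,5,0,total,0,0,127
SYN080,17,male,6,0,1,0.4167,0.1667,5,2,total,1,0,22
SYN081,18,female,4.3,0,1,0,0,0,0,total,0,0,65
SYN082,12,female,2.7,0,0,0.3333,0.3333,4,4,total,0,0,50
SYN083,15,female,2.4,0,0,0.3333,0.2,5,3,lobectomy,0,1,66
SYN084,14,female,0.9,0,0,0.4444,0.2222,4,2,total,0,0,37
SYN085,13,male,0.8,0,0,0.3333,0,6,0,lobectomy,1,1,58
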