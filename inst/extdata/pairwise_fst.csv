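,DAI,TAI,MAT,TEU,TOD,CH,MID,STL,LU,SGG,MO,TRI,PI,CL,DE,PR,AN
DAI,,0.044,0.026,0.117,0.046,0.264,0.254,0.252,0.301,0.288,0.214,0.254,0.258,0.196,0.166,0.213,0.174
TAI,0.013,,0.075,0.228,0.107,0.202,0.215,0.254,0.254,0.284,0.188,0.251,0.221,0.138,0.152,0.192,0.166
MAT,0.008,0.022,,0.122,0.034,0.205,0.196,0.212,0.246,0.245,0.175,0.166,0.237,0.168,0.158,0.188,0.174
TEU,0.036,0.071,0.038,,0.034,0.302,0.272,0.284,0.307,0.275,0.269,0.223,0.248,0.293,0.305,0.283,0.244
TOD,0.014,0.032,0.010,0.011,,0.234,0.196,0.218,0.274,0.250,0.191,0.175,0.217,0.191,0.166,0.203,0.200
CH,0.086,0.067,0.067,0.105,0.078,,0.009,0.010,0.008,0.013,0.045,0.037,0.000,0.034,0.070,0.019,0.051
MID,0.083,0.071,0.064,0.093,0.065,0.003,,0.037,0.005,0.009,0.062,0.037,0.019,0.053,0.080,0.076,0.093
STL,0.070,0.075,0.064,0.090,0.066,0.003,0.012,,0.045,0.041,0.052,0.029,0.027,0.031,0.054,0.062,0.039
LU,0.104,0.090,0.086,0.112,0.098,0.003,0.002,0.016,,0.000,0.098,0.064,0.012,0.066,0.124,0.097,0.136
SGG,0.098,0.098,0.084,0.098,0.087,0.005,0.003,0.014,0.000,,0.077,0.036,0.005,0.075,0.104,0.061,0.094
MO,0.070,0.062,0.057,0.093,0.064,0.016,0.022,0.017,0.037,0.028,,0.064,0.062,0.026,0.103,0.061,0.052
TRI,0.081,0.081,0.055,0.076,0.058,0.013,0.013,0.010,0.024,0.013,0.023,,0.033,0.081,0.098,0.099,0.103
PI,0.084,0.073,0.078,0.085,0.072,0.000,0.007,0.009,0.004,0.002,0.022,0.012,,0.043,0.103,0.069,0.074
CL,0.056,0.039,0.048,0.089,0.055,0.011,0.017,0.009,0.022,0.025,0.008,0.025,0.014,,0.030,0.033,0.061
DE,0.048,0.044,0.047,0.095,0.049,0.023,0.026,0.016,0.043,0.035,0.034,0.032,0.034,0.009,,0.032,0.024
PR,0.066,0.060,0.059,0.094,0.064,0.007,0.026,0.020,0.035,0.022,0.021,0.034,0.024,0.010,0.010,,0.037
AN,0.052,0.049,0.052,0.077,0.060,0.017,0.031,0.012,0.048,0.032,0.017,0.033,0.024,0.018,0.007,0.012,
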