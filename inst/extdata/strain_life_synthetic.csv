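"strain","cycles_to_failure","runout"
0.248,1e+05,TRUE
0.28,18883999,FALSE
0.288,10423216,FALSE
0.294,5829913,FALSE
0.297,1e+05,TRUE
0.308,2900604,FALSE
0.324,1e+05,TRUE
0.327,1728648,FALSE
0.329,1e+05,TRUE
0.335,1553667,FALSE
0.336,1e+05,TRUE
0.337,1e+05,TRUE
0.351,1208609,FALSE
0.358,361145,FALSE
0.367,315839,FALSE
0.369,495924,FALSE
0.371,344772,FALSE
0.377,217770,FALSE
0.381,279394,FALSE
0.404,97354,FALSE
0.417,85832,FALSE
0.428,74007,FALSE
0.431,70343,FALSE
0.433,36386,FALSE
0.457,28336,FALSE
0.459,31877,FALSE
0.459,24137,FALSE
0.501,8282,FALSE
0.51,4155,FALSE
0.522,6051,FALSE
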