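,Chowiet,Middleton,St. Lazaria,Lucy,S'Gang Gwaay,Triangle,Pine,Cleland,Protection,Destruction,Farallones,Año Nuevo
Chowiet,,0.92,0.65,0.37,0.38,0.40,0.21,0.10,0.54,0.05,0.01,0.04
Middleton,,,0.74,0.37,0.37,0.39,0.12,0.07,0.46,0.03,0.02,0.04
St. Lazaria,,,,0.88,0.99,0.99,0.47,0.16,1.10,0.12,0.02,0.05
Lucy,,,,,1.34,1.22,0.92,0.54,0.90,0.13,0.10,0.22
S'Gang Gwaay,,,,,,1.26,0.92,0.56,0.96,0.18,0.10,0.21
Triangle,,,,,,,0.83,0.62,0.88,0.17,0.13,0.27
Pine,,,,,,,,0.72,0.70,0.34,0.15,0.33
Cleland,,,,,,,,,0.31,0.34,0.46,0.78
Protection,,,,,,,,,,0.17,0.03,0.12
Destruction,,,,,,,,,,,0.15,0.24
Farallones,,,,,,,,,,,,1.10
Año Nuevo,,,,,,,,,,,,
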