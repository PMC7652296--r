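colony,year,deployed,retrieved,retrieved_pct,track_files
Chowiet,2014,14,5,35.7,4
Middleton,2014,20,16,75.0,16
St. Lazaria,2014,17,8,47.1,8
Lucy,2014,25,12,48.0,12
Lucy,2015,30,12,40.0,12
Moore,2015,5,0,0.0,0
S'Gang Gwaay,2014,30,11,36.7,10
S'Gang Gwaay,2015,31,14,45.2,14
Triangle,2014,30,13,43.3,12
Triangle,2015,31,16,51.6,16
Pine,2014,30,4,13.3,4
Pine,2015,22,5,22.7,4
Cleland,2014,20,2,10.0,2
Protection,2015,23,9,39.1,7
Destruction,2015,7,2,28.6,2
Farallones,2014,20,9,45.0,9
Año Nuevo,2014,15,12,80.0,9
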