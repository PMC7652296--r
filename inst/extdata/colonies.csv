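name,abbrev,location,region,pairs,lat,lon
Daikoku,DAI,Japan,west,78000,42.954744,144.866057
Taijima,TAI,Japan,west,150,41.263284,140.345585
Matsumae-Kojima,MAT,Japan,west,40000,41.360155,139.818113
Teuri,TEU,Japan,west,379000,44.417646,141.312281
Todojima,TOD,Japan,west,35000,45.366808,141.035141
Chowiet,CH,Alaska,east,400,56.015513,-156.740272
Middleton,MID,Alaska,east,10000,59.415254,-146.345472
St. Lazaria,STL,Alaska,east,2000,56.986502,-135.710838
Lucy,LU,British Columbia,east,25000,54.294418,-130.621907
S'Gang Gwaay,SGG,British Columbia,east,14000,52.092634,-131.225633
Moore,MO,British Columbia,east,40000,52.678344,-129.418847
Triangle,TRI,British Columbia,east,42000,50.851023,-129.066292
Pine,PI,British Columbia,east,90000,50.976062,-127.729909
Cleland,CL,British Columbia,east,1000,49.171516,-126.091075
Destruction,DE,Washington,east,6500,47.674599,-124.484817
Protection,PR,Washington,east,36000,48.126341,-122.930289
Southeast Farallon,SEF,California,east,4500,37.695357,-123.000752
Año Nuevo,AN,California,east,330,37.107584,-122.337026
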