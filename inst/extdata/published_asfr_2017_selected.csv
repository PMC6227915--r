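location,age_start,age_end,asfr_per_1000
Global,10,15,0.81
Global,15,20,42.9
Global,20,25,129.4
Global,25,30,131.9
Global,30,35,96.8
Global,35,40,52.4
Global,40,45,17.2
Global,45,50,3.4
Global,50,55,0.06
Niger,10,15,3.2
Niger,15,20,174.9
Niger,20,25,303.5
Niger,25,30,315.5
Niger,30,35,278.4
Niger,35,40,201.2
Niger,40,45,101.9
Niger,45,50,37.3
Niger,50,55,0.72
Cyprus,10,15,0.03
Cyprus,15,20,4.0
Cyprus,20,25,24.5
Cyprus,25,30,58.8
Cyprus,30,35,68.3
Cyprus,35,40,35.9
Cyprus,40,45,9.3
Cyprus,45,50,1.1
Cyprus,50,55,0.02
South Korea,10,15,0.02
South Korea,15,20,1.7
South Korea,20,25,13.5
South Korea,25,30,60.6
South Korea,30,35,117.4
South Korea,35,40,48.9
South Korea,40,45,6.1
South Korea,45,50,0.24
South Korea,50,55,0.0
Puerto Rico,10,15,0.74
Puerto Rico,15,20,30.9
Puerto Rico,20,25,75.5
Puerto Rico,25,30,65.2
Puerto Rico,30,35,43.5
Puerto Rico,35,40,21.0
Puerto Rico,40,45,4.7
Puerto Rico,45,50,0.15
Puerto Rico,50,55,0.0
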