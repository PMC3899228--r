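site,species,sea_state,radius_m
A,porpoise,0,1600
A,porpoise,1,1400
A,porpoise,2,1100
A,rissos,0,2200
A,rissos,1,2000
A,rissos,2,1700
B,porpoise,0,1600
B,porpoise,1,1400
B,porpoise,2,1100
B,rissos,0,2200
B,rissos,1,2000
B,rissos,2,1700
C-1,porpoise,0,2000
C-1,porpoise,1,1800
C-1,porpoise,2,1400
C-1,rissos,0,2800
C-1,rissos,1,2500
C-1,rissos,2,2100
C-2,porpoise,0,2000
C-2,porpoise,1,1800
C-2,porpoise,2,1400
C-2,rissos,0,2600
C-2,rissos,1,2300
C-2,rissos,2,2000
D,porpoise,0,2400
D,porpoise,1,2100
D,porpoise,2,1600
D,rissos,0,3000
D,rissos,1,2700
D,rissos,2,2300
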