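term,CVLL,dCVLL,retained
Site,-3036.86,NA,TRUE
Sea State,-2953.44,83.42,TRUE
s(SD of current speed),-2906.52,46.92,TRUE
s(Hour of day),-2872.70,33.82,TRUE
s(Slope),-2855.48,17.22,TRUE
s(Depth),-2843.52,11.96,TRUE
s(Tidal stratification),-2834.70,8.83,TRUE
s(Aspect),-2824.53,10.16,TRUE
s(SD of slope),-2840.46,-15.92,FALSE
s(Current direction),-2861.82,-21.36,FALSE
s(Mean stratification),-2892.66,-30.84,FALSE
s(Tidal state),-2927.68,-35.02,FALSE
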