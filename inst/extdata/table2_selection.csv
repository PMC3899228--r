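term,CVLL,dCVLL,retained
Sea State,-9645.54,NA,TRUE
"te(X,Y)",-9524.84,120.70,TRUE
Site,-9421.26,103.58,TRUE
s(Lunar cycle),-9336.61,84.65,TRUE
s(Mean stratification),-9305.75,30.86,TRUE
s(Day of year),-9285.25,20.50,TRUE
s(Depth),-9267.39,17.85,TRUE
s(Aspect),-9252.76,14.64,TRUE
s(Tidal state),-9241.04,11.72,TRUE
s(Slope),-9240.30,0.74,TRUE
s(Year),-9241.38,-1.08,FALSE
s(Hour of day),-9249.61,-8.23,FALSE
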