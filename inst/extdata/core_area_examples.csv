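species,region,contour_level,contour_km2,survey_km2,reported_pct
porpoise,east,50,2.8,14.6,19
porpoise,sound,50,0.9,14.6,6
rissos,west,50,2.6,34.31,8
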