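state,latitude,longitude,population
AL,32.8,-86.8,4822000
AK,64.0,-152.0,731000
AZ,34.2,-111.6,6553000
AR,34.9,-92.4,2949000
CA,37.2,-119.3,38041000
CO,39.0,-105.5,5188000
CT,41.6,-72.7,3590000
DE,39.0,-75.5,917000
FL,28.6,-82.4,19318000
GA,32.6,-83.4,9920000
HI,20.3,-156.4,1392000
ID,44.4,-114.6,1596000
IL,40.0,-89.2,12875000
IN,39.9,-86.3,6537000
IA,42.1,-93.5,3074000
KS,38.5,-98.4,2886000
KY,37.5,-85.3,4380000
LA,31.0,-92.0,4602000
ME,45.4,-69.2,1329000
MD,39.0,-76.8,5885000
MA,42.3,-71.8,6646000
MI,44.3,-85.4,9883000
MN,46.3,-94.3,5379000
MS,32.7,-89.7,2985000
MO,38.4,-92.5,6022000
MT,47.0,-109.6,1005000
NE,41.5,-99.8,1856000
NV,39.3,-116.6,2759000
NH,43.7,-71.6,1320000
NJ,40.2,-74.7,8865000
NM,34.4,-106.1,2086000
NY,42.9,-75.5,19570000
NC,35.5,-79.4,9752000
ND,47.4,-100.5,700000
OH,40.3,-82.8,11544000
OK,35.6,-97.5,3815000
OR,43.9,-120.6,3899000
PA,40.9,-77.8,12764000
RI,41.7,-71.5,1050000
SC,33.9,-80.9,4724000
SD,44.4,-100.2,833000
TN,35.9,-86.4,6456000
TX,31.5,-99.3,26059000
UT,39.3,-111.7,2855000
VT,44.1,-72.7,626000
VA,37.5,-78.9,8186000
WA,47.4,-120.4,6897000
WV,38.6,-80.6,1856000
WI,44.6,-89.9,5726000
WY,43.0,-107.5,576000
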