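provenance,latitude,longitude,solar_radiation,elevation,mat,temp_seasonality,annual_precip,precip_seasonality,region
GRF,35.32,-82.86,14772,1607,8.94,644.17,1968,8.48,northern
PSG,35.42,-82.74,14814,1515,9.43,656.84,1855,8.47,northern
HWK,35.91,-81.87,14813,885,11.72,724.27,1322,10.48,northern
SPB,32.85,-84.48,15901,206,17.05,705.63,1284,20.31,southern
PRV,32.07,-84.91,16103,190,17.54,684.34,1283,23.12,southern
HI,31.72,-87.46,16205,73,18.08,690.91,1476,21.97,southern
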