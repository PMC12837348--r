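-BEGIN HEADER-
Synthetic NASA-POWER-style daily point extract (generated example, not real data)
Parameters:
T2M Temperature at 2 Meters (C) ;
RH2M Relative Humidity at 2 Meters (%) ;
WS2M Wind Speed at 2 Meters (m/s) ;
ALLSKY_SFC_SW_DWN All Sky Surface Shortwave Downward Irradiance (W/m^2) ;
-END HEADER-
YEAR,MO,DY,T2M,RH2M,WS2M,ALLSKY_SFC_SW_DWN
2023,1,1,28.4,81.2,1.6,241.0
2023,1,2,29.1,79.8,1.4,238.5
2023,1,3,30.3,78.5,1.2,252.3
2023,1,4,31.0,-999,1.3,260.1
2023,1,5,29.6,80.4,1.7,247.9
2023,1,6,28.8,82.1,1.5,236.4
2023,1,7,28.1,83.0,1.8,230.2
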