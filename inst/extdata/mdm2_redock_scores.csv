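ligand,MOE_MDM4,MOE_BCL2,MOE_MDM2_p1,MOE_MDM2_p2,Vina_MDM2,GOLD_MDM2
MP,-9.6,-6.6,-7.6,-7.1,-7.7,72.7
OT,-9.4,-7.4,-7.5,-6.9,-8.1,64.0
AT,-11.1,-7.3,-8.4,-8.1,-7.8,61.4
BI,-10.1,-7.1,-7.4,-7.5,-8.0,65.4
DR,-9.3,-6.4,-7.2,-6.8,-8.0,72.1
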