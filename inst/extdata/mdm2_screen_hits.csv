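id,name,mechanism,affinity,pic50
MP,MePPEP,CB1 antagonist,-7.43,6.08
OT,Otenabant,CB1 antagonist,-7.36,6.45
AT,Atorvastatin,HMG-CoA reductase inhibitor,-7.79,7.10
BI,BIRT-2584,ITGAL and ITGB2 antagonist,-6.79,8.27
DR,Drinabant,CB1 antagonist,-6.90,7.88
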