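variant,phenotype,dosage,n,mean,sd
rs891512,SBP,0,13,0.6,13.7
rs891512,SBP,1,1,-29.8,NA
rs891512,DBP,0,13,0.6,7.6
rs891512,DBP,1,1,-19.7,NA
rs867225,SBP,0,9,4.72,9.5
rs867225,SBP,1,5,-12.8,18.7
rs867225,DBP,0,9,3.3,5.4
rs867225,DBP,1,5,-8.4,10.0
rs743507,SBP,0,9,6.1,8.8
rs743507,SBP,1,5,-15.2,16.1
rs41483644,SBP,0,13,0.9,13.1
rs41483644,SBP,1,1,-32.8,NA
rs41483644,DBP,0,13,0.4,8.1
rs41483644,DBP,1,1,-17.2,NA
rs3730009,DBP,0,7,4.4,5.6
rs3730009,DBP,1,6,-5.9,9.9
rs3730009,DBP,2,1,-7.5,NA
rs77325852,DBP,0,8,3.6,5.7
rs77325852,DBP,1,5,-6.7,10.9
rs77325852,DBP,2,1,-7.5,NA
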