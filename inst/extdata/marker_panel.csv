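name,class_tag,formula,adduct,association,printed_mz,flagged
PS 36:1,PS,C42H80NO10P,[M-H]-,lower_TCP,788.5,FALSE
ST 24:1,ST,C48H91NO11S,[M-H]-,lower_TCP,888.6,FALSE
ST 24:1(OH),ST,C48H91NO12S,[M-H]-,lower_TCP,904.6,FALSE
ST 26:1,ST,C50H95NO11S,[M-H]-,lower_TCP,916.7,FALSE
ST 22:0,ST,C46H89NO11S,[M-H]-,lower_TCP,862.6,FALSE
ST 22:1,ST,C46H87NO11S,[M-H]-,lower_TCP,860.6,FALSE
ST 18:0,ST,C42H81NO11S,[M-H]-,lower_TCP,806.5,FALSE
plasmenyl-PE 38:2,plasmenyl-PE,C43H82NO7P,[M-H]-,lower_TCP,754.6,FALSE
plasmenyl-PE 36:2,plasmenyl-PE,C41H78NO7P,[M-H]-,lower_TCP,726.5,FALSE
plasmenyl-PE 34:1,plasmenyl-PE,C39H76NO7P,[M-H]-,lower_TCP,700.5,FALSE
PE 38:4,PE,C43H78NO8P,[M-H]-,higher_TCP,766.5,FALSE
PC 34:1,PC,C42H82NO8P,[M+Cl]-,higher_TCP,794.5,FALSE
PI 38:4,PI,C47H83O13P,[M-H]-,higher_TCP,885.6,TRUE
PS 40:6,PS,C46H78NO10P,[M-H]-,higher_TCP,834.5,FALSE
PE 40:6,PE,C45H78NO8P,[M-H]-,higher_TCP,790.5,FALSE
plasmenyl-PE 40:6,plasmenyl-PE,C45H78NO7P,[M-H]-,higher_TCP,774.6,TRUE
plasmenyl-PE 38:4,plasmenyl-PE,C43H78NO7P,[M-H]-,higher_TCP,750.5,FALSE
plasmenyl-PE 38:6,plasmenyl-PE,C43H74NO7P,[M-H]-,higher_TCP,746.5,FALSE
plasmenyl-PE 36:4,plasmenyl-PE,C41H74NO7P,[M-H]-,higher_TCP,722.5,FALSE
Cer 40:2,Cer,C40H77NO3,[M+Cl]-,higher_TCP,654.6,FALSE
Cer 38:1,Cer,C38H75NO3,[M+Cl]-,higher_TCP,628.5,FALSE
Cer 36:1,Cer,C36H71NO3,[M+Cl]-,higher_TCP,600.5,FALSE
Cer 36:2,Cer,C36H69NO3,[M+Cl]-,higher_TCP,598.5,FALSE
Cer 34:1,Cer,C34H67NO3,[M+Cl]-,higher_TCP,572.5,FALSE
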