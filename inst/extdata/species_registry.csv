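species,guild,mean_mass_g,weight
DS,kangaroo_rat,120,0.1
DM,kangaroo_rat,43,0.65
DO,kangaroo_rat,48,0.25
BA,small_granivore,8,0.03
PB,small_granivore,30,1
PH,small_granivore,31,0.02
PI,small_granivore,15,0.05
PP,small_granivore,16,0.3
PF,small_granivore,7,0.15
PE,small_granivore,21,0.1
PL,small_granivore,20,0.05
PM,small_granivore,21,0.1
RF,small_granivore,13,0.03
RM,small_granivore,10,0.15
RO,small_granivore,9,0.02
OT,other,24,0.5
OL,other,32,0.2
SH,other,70,0.2
NTA,other,160,0.1
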