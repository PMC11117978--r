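hlt,comparator,ror,ci_low,ci_high,direction
modified_dose,LIR,1.6169,1.3379,1.9542,higher
modified_dose,TIR,1.5200,1.0032,2.3031,higher
modified_dose,EXE,0.4087,0.3579,0.4667,lower
modified_dose,ALL_OTHER,0.7722,0.6823,0.8740,lower
overdose,EXE,2.4174,1.8878,3.0956,higher
overdose,LIR,1.7434,1.3913,2.1845,higher
overdose,TIR,3.3868,1.6736,6.8535,higher
overdose,ALL_OTHER,1.4764,1.2608,1.7288,higher
off_label_use,ALB,4.4375,2.6615,7.3988,higher
off_label_use,DUL,8.3830,7.3359,9.5796,higher
off_label_use,EXE,2.9018,2.6680,3.1560,higher
off_label_use,LIR,2.8377,2.6052,3.0910,higher
off_label_use,LIX,6.5330,3.2525,13.1221,higher
off_label_use,ALL_OTHER,3.3226,3.1270,3.5304,higher
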