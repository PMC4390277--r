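label,mean,sd,n
trizol_mir21_op1,-1.83,2.60,32
trizol_mir21_op2,0.05,2.01,32
mirneasy_mir485_op1,-2.60,2.02,32
mirneasy_mir485_op2,-1.31,2.26,32
mirneasy_mir21_op1,-7.59,1.75,32
mirneasy_mir21_op2,-6.69,1.85,32
absddct_mir142_trizol,1.69,1.83,32
absddct_mir142_mirneasy,0.91,0.89,32
absddct_total_trizol,1.79,1.63,595
absddct_total_mirneasy,1.12,0.99,703
rna_conc_trizol,19,12,32
rna_conc_mirneasy,353,85,32
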