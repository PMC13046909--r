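material,kv,fat_ring,dose_pct,delta_base,der,alpha
iodine,140,FALSE,100,-5.72,2.48,26.45
iodine,140,FALSE,120,-5.77,2.48,26.45
iodine,140,FALSE,200,-7.25,2.48,26.43
iodine,120,FALSE,100,-5.01,2.08,26.23
iodine,120,FALSE,120,-5.78,2.08,26.17
iodine,120,FALSE,200,-7.45,2.09,26.18
iodine,140,TRUE,100,-4.20,2.52,26.94
iodine,140,TRUE,120,-4.95,2.50,26.65
iodine,140,TRUE,200,-6.55,2.50,26.59
iodine,120,TRUE,100,-4.47,2.11,26.40
iodine,120,TRUE,120,-5.47,2.11,26.42
iodine,120,TRUE,200,-7.72,2.12,26.33
iron,140,FALSE,100,-3.85,2.18,4.30
iron,140,FALSE,120,-4.16,2.15,4.30
iron,140,FALSE,200,-5.77,2.17,4.30
iron,120,FALSE,100,-4.24,1.95,4.03
iron,120,FALSE,120,-4.58,1.91,4.05
iron,120,FALSE,200,-5.64,1.92,4.02
iron,140,TRUE,100,-3.39,2.20,4.36
iron,140,TRUE,120,-3.19,2.22,4.35
iron,140,TRUE,200,-4.23,2.16,4.32
iron,120,TRUE,100,-2.66,1.93,4.12
iron,120,TRUE,120,-3.50,1.96,4.07
iron,120,TRUE,200,-4.64,1.91,4.09
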