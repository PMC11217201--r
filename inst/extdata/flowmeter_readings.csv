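measurement_id,system,session,qpump_ml_min,constriction_fraction,qcyl_nominal_ml_min,qtube_nominal_ml_min,qcyl_measured_ml_min,qtube_measured_ml_min
150-20,DMI-20,test,150,0.2,30,120,31,124
150-20,DMI-20,retest,150,0.2,30,120,30,127
150-20,Vision-600,test,150,0.2,30,120,33,118
150-20,Vision-600,retest,150,0.2,30,120,30,119
150-40,DMI-20,test,150,0.4,60,90,61,98
150-40,DMI-20,retest,150,0.4,60,90,59,99
150-40,Vision-600,test,150,0.4,60,90,61,87
150-40,Vision-600,retest,150,0.4,60,90,61,81
150-60,DMI-20,test,150,0.6,90,60,91,63
150-60,DMI-20,retest,150,0.6,90,60,94,61
150-60,Vision-600,test,150,0.6,90,60,94,60
150-60,Vision-600,retest,150,0.6,90,60,85,58
150-80,DMI-20,test,150,0.8,120,30,119,32
150-80,DMI-20,retest,150,0.8,120,30,120,31
150-80,Vision-600,test,150,0.8,120,30,126,31
150-80,Vision-600,retest,150,0.8,120,30,125,26
200-20,DMI-20,test,200,0.2,40,160,41,171
200-20,DMI-20,retest,200,0.2,40,160,43,168
200-20,Vision-600,test,200,0.2,40,160,39,173
200-20,Vision-600,retest,200,0.2,40,160,42,158
200-40,DMI-20,test,200,0.4,80,120,80,132
200-40,DMI-20,retest,200,0.4,80,120,80,134
200-40,Vision-600,test,200,0.4,80,120,100,122
200-40,Vision-600,retest,200,0.4,80,120,81,119
200-60,DMI-20,test,200,0.6,120,80,126,83
200-60,DMI-20,retest,200,0.6,120,80,131,80
200-60,Vision-600,test,200,0.6,120,80,125,86
200-60,Vision-600,retest,200,0.6,120,80,122,84
200-80,DMI-20,test,200,0.8,160,40,163,41
200-80,DMI-20,retest,200,0.8,160,40,162,42
200-80,Vision-600,test,200,0.8,160,40,166,39
200-80,Vision-600,retest,200,0.8,160,40,164,31
250-20,DMI-20,test,250,0.2,50,200,49,200
250-20,DMI-20,retest,250,0.2,50,200,47,203
250-20,Vision-600,test,250,0.2,50,200,51,222
250-20,Vision-600,retest,250,0.2,50,200,50,211
250-40,DMI-20,test,250,0.4,100,150,102,162
250-40,DMI-20,retest,250,0.4,100,150,99,166
250-40,Vision-600,test,250,0.4,100,150,101,182
250-40,Vision-600,retest,250,0.4,100,150,100,163
250-60,DMI-20,test,250,0.6,150,100,153,103
250-60,DMI-20,retest,250,0.6,150,100,160,100
250-60,Vision-600,test,250,0.6,150,100,174,104
250-60,Vision-600,retest,250,0.6,150,100,146,114
250-80,DMI-20,test,250,0.8,200,50,200,52
250-80,DMI-20,retest,250,0.8,200,50,204,53
250-80,Vision-600,test,250,0.8,200,50,222,56
250-80,Vision-600,retest,250,0.8,200,50,218,43
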