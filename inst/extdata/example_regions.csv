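region_id,time_h,dose_rate_gy_per_h
kidney_left,1,0.62
kidney_left,4,0.55
kidney_left,24,0.31
kidney_left,72,0.08
tumor_1,1,0.747
tumor_1,4,1.576
tumor_1,24,1.238
tumor_1,72,0.555
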