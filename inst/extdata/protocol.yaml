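# Acquisition protocol constants of the packaged flow-phantom study
requested_activity_MBq: 500
vcyl_ml: 160
v_input_ml: 15.7
half_life_s: 122.24
frame_counts: [14, 3, 3, 4]
frame_durations_s: [5, 10, 20, 30]
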