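file,n_rows,numeric_checksum
flowmeter_readings.csv,48,29197
injected_activities.csv,24,24047.72
modelled_flows.csv,48,11531
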