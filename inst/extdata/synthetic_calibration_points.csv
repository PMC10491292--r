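"temperature_c","humidity_pct","label"
36,67.8297977290724,"high-humidity"
38,58.2425826542221,"high-humidity"
40,51.0445659916516,"high-humidity"
42,42.8701656390906,"high-heat"
44,33.2234613271044,"high-heat"
46,23.2421760438175,"high-heat"
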