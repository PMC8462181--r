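"species","wing_length","eye_area","iridescence","eyespots"
"spA",21.5,2.1,0,1
"spB",34.2,3.3,1,1
"spC",28,2.8,1,0
"spD",25.3,2.2,0,0
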