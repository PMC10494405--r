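"code","description"
"999007001","Neuropathic pain"
"999007002","Neuropathy"
"999007003","Peripheral neuropathy"
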