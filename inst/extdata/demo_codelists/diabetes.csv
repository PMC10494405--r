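"code","description"
"999010001","Type 1 diabetes mellitus"
"999010002","Type 2 diabetes mellitus"
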