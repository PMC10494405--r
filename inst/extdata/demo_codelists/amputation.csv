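"code","description"
"999008001","Amputation of lower limb"
"999008002","Amputation of upper limb"
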