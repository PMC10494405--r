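"code","description"
"999005001","Post-herpetic neuralgia"
"999005002","Post-zoster neuropathy"
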