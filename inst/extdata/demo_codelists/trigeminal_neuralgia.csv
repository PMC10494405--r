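"code","description"
"999003001","Trigeminal neuralgia"
"999003002","Atypical trigeminal neuralgia"
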