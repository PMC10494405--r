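"code","description"
"999006001","Phantom limb pain"
"999006002","Phantom limb syndrome with pain"
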