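"code","description"
"999011001","Epilepsy"
"999011002","Focal epilepsy"
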