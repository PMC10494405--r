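"code","description"
"999009001","Diabetic neuropathy"
"999009002","Diabetic polyneuropathy"
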