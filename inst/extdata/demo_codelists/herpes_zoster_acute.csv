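"code","description"
"999004001","Acute herpes zoster"
"999004002","Herpes zoster ophthalmicus"
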