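"code","description"
"999001001","Ankylosing spondylitis"
"999001002","Chronic low back pain"
"999001003","Chronic osteomyelitis"
"999001004","Chronic pain"
"999001005","Complex regional pain syndrome"
"999001006","Fibromyalgia"
"999001007","Fibrositis"
"999001008","Periostitis"
"999001009","Rheumatic pain"
"999001010","Rheumatism"
"999001011","Rheumatoid arthritis"
"999001012","Still's disease"
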