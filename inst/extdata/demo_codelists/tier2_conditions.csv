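"code","description"
"999002001","Arthrosis/arthritis/arthralgia/arthropathy (excl. reactive/transient)"
"999002002","Cervicocranial/cervicobrachial syndrome"
"999002003","Coccygodynia"
"999002004","Connective tissue disorders"
"999002005","Dysmenorrhoea"
"999002006","Endometriosis"
"999002007","Familial chondrocalcinosis"
"999002008","Migraine"
"999002009","Myositis (excl. infective causes)"
"999002010","Osteoarthritis"
"999002011","Osteochondritis"
"999002012","Osteoporosis (incl. fragility fracture and collapsed vertebra)"
"999002013","Pain/ache of different body parts/general aches and pains"
"999002014","Pathological fracture"
"999002015","Polymyalgia rheumatica/PMR/GCA"
"999002016","Radiculopathy (incl. cauda equina compression)/radiculitis"
"999002017","Sciatica"
"999002018","Spinal stenosis"
"999002019","Spondylopathy/spondylosis/spondylolisthesis"
"999002020","Systemic lupus erythematosus"
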