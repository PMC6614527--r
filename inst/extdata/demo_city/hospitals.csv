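"id","name","lat","lon","ecr_capable"
"H1","Hospital 1",-33.8253126799898,151.045734702863,TRUE
"H2","Hospital 2",-33.9806591285093,151.07981836351,TRUE
"H3","Hospital 3",-33.7603477708237,151.237977643641,TRUE
"H4","Hospital 4",-34.003510879115,151.259680499558,TRUE
"H5","Hospital 5",-33.8813258312932,151.401313261397,TRUE
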