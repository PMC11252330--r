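view,score,band,count
lateral,0,75%,28
lateral,0,100%,131
lateral,1,75%,30
lateral,1,100%,43
lateral,2,75%,19
lateral,2,100%,23
lateral,3,75%,4
lateral,3,100%,3
dorsal,0,75%,27
dorsal,0,100%,97
dorsal,1,75%,26
dorsal,1,100%,40
dorsal,2,75%,19
dorsal,2,100%,21
dorsal,3,75%,3
dorsal,3,100%,4
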