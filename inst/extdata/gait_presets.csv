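score,speed,stride_freq,stride_amp,lift_amp,asymmetry,affected_limb,head_amp,arch_amp,sway_amp,noise_sd
0,8.0,0.05,40,15,0.00,none,0,0,6,1.5
1,7.0,0.05,40,15,0.15,hind_left,8,4,8,1.5
2,5.5,0.05,40,14,0.35,hind_left,16,9,10,1.5
3,3.5,0.05,38,12,0.55,hind_left,24,15,12,1.5
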