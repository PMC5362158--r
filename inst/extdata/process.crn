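# enzymatic reaction process at nominal rates
# input clamped for open-loop study
xin + xe -> xi @ kr1=0.005
xi -> xout + xe @ kr2=1.6
xout -> empty @ kr3=8e-04
clamp: xin
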