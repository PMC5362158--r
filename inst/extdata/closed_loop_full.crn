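# full inverse-feedforward + PI closed-loop tracking circuit (26 reactions)
r -> r + x1 @ gGa_k=0.00128
x1 -> empty @ gGa=1
r -> r + x2 @ gGd_k=4e-06
x2 -> empty @ gGd=1
beta -> beta + x3 @ gSbI=1
xs + x3 -> empty @ gSbI=1
x2 -> x2 + xs @ gSbI=1
x3 -> empty @ gSbI=1
x1 -> x1 + x4 @ gD=1
x3 + x4 -> x3 @ gD=1
x7 -> x7 + x8 @ KI=2.5e-08
x7 -> x7 + x9 @ gGKP_k=0.02
x9 -> empty @ gGKP=1
x8 -> x8 + x10 @ gSmI=4e-04
x9 -> x9 + x10 @ gSmI=4e-04
x10 -> empty @ gSmI=4e-04
r -> r + x7 @ gSbII=3
xt + x7 -> empty @ gSbII=3
x6 -> x6 + xt @ gSbII=3
x7 -> empty @ gSbII=3
x4 -> x4 + x5 @ gSmII=1
x10 -> x10 + x5 @ gSmII=1
x5 -> empty @ gSmII=1
x5 + xe -> xi + x5 @ kr1=0.005
xi -> x6 + xe @ kr2=1.6
x6 -> empty @ kr3=8e-04
clamp: r, beta
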