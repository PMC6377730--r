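# FitzHugh-Nagumo spiking-neuron model in the plain-text model format.
# Two states, three parameters, one observable.
name fhn_example
state V' = g*(V - V^3/3 + R)
state R' = -(1/g)*(V - a + b*R)
init V = -1
init R = 1
param a in [1e-5, 1e5]
param b in [1e-5, 1e5]
param g in [1e-5, 1e5]
obs y1 = V
horizon 20
points 6
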