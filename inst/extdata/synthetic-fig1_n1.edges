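# Synthetic reconstruction of a published figure network (the figure itself is
# not machine-readable); the topology is pinned by its documented facts:
# C =1= E, D =1= F, H =1= J, H =2= J, all order-3 classes singletons,
# and the pair (n1, n2) is second-order indistinguishable but not isomorphic.
edge R A
edge R C
edge R F
edge A H
edge A J
edge H C
edge H D
edge J E
edge J F
edge C 1
edge C 2
edge E 1
edge E 2
edge D 3
edge D 4
edge F 3
edge F 4
leaf 1 1
leaf 2 2
leaf 3 3
leaf 4 4
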