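# Synthetic reconstruction of a published counterexample network: A and B
# share both their parent set {X, Y} and their child set {1, 2}, so A and B
# are kth-order equivalent for every k and the network is not kth-order
# reduced for any k.
edge R X
edge R Y
edge X A
edge X B
edge X 3
edge Y A
edge Y B
edge A 1
edge A 2
edge B 1
edge B 2
leaf 1 1
leaf 2 2
leaf 3 3
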