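# Synthetic reconstruction of a published figure network (13 nodes, taxa 1-6).
# Documented facts: order-1 classes are singletons; exactly R, B, F have no
# first-order equivalent in the 15-node partner; every other node has exactly
# one. (The source text attaches the two unpaired sets to the opposite
# networks, which is arithmetically inconsistent with the printed node counts
# and discordance sum 8; the assignment here is the consistent one.)
edge R B
edge R A
edge B G
edge B F
edge G A
edge G C
edge F C
edge F D
edge A 1
edge A 2
edge C 3
edge C 4
edge D 5
edge D 6
leaf 1 1
leaf 2 2
leaf 3 3
leaf 4 4
leaf 5 5
leaf 6 6
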