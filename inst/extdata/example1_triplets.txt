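# 15 rooted triplets on taxa i..o; not consistent with any tree,
# consistent with a level-1 network with a single reticulation leaf (l)
i j l
j k i
k l j
k l i
n o m
l o k
j l o
m n l
m n j
n o k
m o i
j k n
i j o
i k m
i l n
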