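# 20 rooted triplets on taxa i..n; requires more than one reticulation
j k i
l i j
m j i
j n i
k l i
i k m
i k n
l m i
l n i
m n i
k l j
k m j
j n k
l m j
j l n
m n j
k l m
k l n
m n k
m n l
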