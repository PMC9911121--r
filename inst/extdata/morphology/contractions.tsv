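suffix	lemma	pos
n't	not	neg
'll	will	aux
're	be	aux
've	have	aux
'm	be	aux
's	be	aux
'd	will	aux
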