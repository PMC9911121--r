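plural	singular
children	child
men	man
women	woman
feet	foot
teeth	tooth
mice	mouse
geese	goose
knives	knife
wives	wife
shelves	shelf
loaves	loaf
halves	half
firemen	fireman
policemen	policeman
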