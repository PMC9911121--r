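# distractor vocabulary for the synthetic generator: disjoint from every
# built-in checklist's accepted-lemma set (validated by the test suite)
zebra
violin
galaxy
pencil
crayon
turtle
rocket
jungle
camera
hammer
banana
tiger
lantern
marble
anchor
meadow
pillow
wizard
dolphin
magnet
puzzle
ribbon
tunnel
volcano
wagon
whistle
yogurt
acorn
beaver
candle
dragon
eagle
falcon
guitar
helmet
island
jacket
kettle
lemon
mitten
nickel
orchard
parrot
quilt
raccoon
saddle
trumpet
velvet
walrus
yarn
zipper
basket
canyon
desert
engine
forest
goblet
harbor
igloo
jewel
robot
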