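# regular verbs given full verbal paradigms by the inflection index;
# irregular verbs live in irregular_verbs.tsv
kick
play
look
knock
call
climb
walk
want
need
turn
dance
marry
try
live
like
fit
open
slice
rain
work
jump
help
laugh
happen
ask
talk
start
stop
wait
watch
wash
clean
cook
push
pull
move
stay
use
cry
smile
wave
point
reach
save
rescue
hand
name
bark
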