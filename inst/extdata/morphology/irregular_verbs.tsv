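base	forms
be	am;is;are;was;were;been;being
go	goes;went;gone;going
have	has;had;having
do	does;did;done;doing
say	says;said;saying
make	makes;made;making
take	takes;took;taken;taking
get	gets;got;gotten;getting
come	comes;came;coming
see	sees;saw;seen;seeing
know	knows;knew;known;knowing
think	thinks;thought;thinking
fall	falls;fell;fallen;falling
run	runs;ran;running
sit	sits;sat;sitting
stand	stands;stood;standing
break	breaks;broke;broken;breaking
throw	throws;threw;thrown;throwing
catch	catches;caught;catching
buy	buys;bought;buying
bring	brings;brought;bringing
tell	tells;told;telling
give	gives;gave;given;giving
put	puts;putting
wear	wears;wore;worn;wearing
eat	eats;ate;eaten;eating
find	finds;found;finding
leave	leaves;left;leaving
lose	loses;lost;losing
meet	meets;met;meeting
hear	hears;heard;hearing
keep	keeps;kept;keeping
sleep	sleeps;slept;sleeping
begin	begins;began;begun;beginning
fly	flies;flew;flown;flying
ride	rides;rode;ridden;riding
drive	drives;drove;driven;driving
sweep	sweeps;swept;sweeping
stick	sticks;stuck;sticking
strike	strikes;struck;striking
spread	spreads;spreading
let	lets;letting
cut	cuts;cutting
sing	sings;sang;sung;singing
swim	swims;swam;swum;swimming
feel	feels;felt;feeling
hold	holds;held;holding
wake	wakes;woke;woken;waking
will	would
can	could
shall	should
may	might
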