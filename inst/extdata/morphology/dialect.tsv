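form	expansion
gonna	going;to
wanna	want;to
gotta	got;to
kinda	kind;of
sorta	sort;of
outta	out;of
lemme	let;me
gimme	give;me
hafta	have;to
coulda	could;have
woulda	would;have
shoulda	should;have
dunno	do;not;know
ya	you
won't	will;not
can't	can;not
cannot	can;not
ain't	be;not
let's	let;us
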