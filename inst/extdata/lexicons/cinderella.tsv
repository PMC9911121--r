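# task_id: Cinderella
# provenance: synthetic reconstruction for testing and demonstration; the normative list lives in the published core-lexicon norming studies and should be supplied by the user for real analyses
label	accepted_lemmas	extended_forms
a	a	
after	after	
all	all	
and	and	
at	at	
back	back	
ball	ball	
be	be	
beautiful	beautiful	
because	because	
but	but	
by	by	
carriage	carriage	
castle	castle	
cinderella	cinderella	
clock	clock	
come	come	
dance	dance	
daughter	daughter	
do	do	
dress	dress	
fairy	fairy	
fall	fall	
father	father;dad;daddy;pa;papa	
find	find	
fit	fit	
foot	foot	
for	for	
get	get	
girl	girl	
glass	glass	
go	go	
godmother	godmother	
hand	hand	
have	have	
he	he	
her	her	
home	home	
horse	horse	
house	house	
i	i	
in	in	
into	into	
it	it	
leave	leave	
like	like	
little	little	
live	live	
look	look	
lose	lose	
make	make	
marry	marry	
midnight	midnight	
mother	mother;mom;mama;mommy;ma	
mouse	mouse	
night	night	
not	not	
of	of	
off	off	
on	on	
one	one	
out	out	
prince	prince	
pumpkin	pumpkin	
run	run	
say	say	
she	she	
shoe	shoe	
sister	sister	
slipper	slipper	
so	so	
stepmother	stepmother	
stepsister	stepsister	
strike	strike	
take	take	
tell	tell	
that	that	
the	the	
then	then	
there	there	
they	they	
time	time	
to	to	
try	try	
turn	turn	
two	two	
ugly	ugly	
up	up	
want	want	
wear	wear	
when	when	
who	who	
will	will	
with	with	
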