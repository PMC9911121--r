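# task_id: RefusedUmbrella
# provenance: synthetic reconstruction for testing and demonstration; the normative list lives in the published core-lexicon norming studies and should be supplied by the user for real analyses
label	accepted_lemmas	extended_forms
a	a	
and	and	
back	back	
be	be	
boy	boy	
but	but	
do	do	
get	get	
go	go	
have	have	
he	he	
home	home	
i	i	
in	in	
it	it	
little	little	
mother	mother;mom;mama;mommy;ma	
need	need	
no	no	
not	not	
of	of	
out	out	
rain	rain	
say	say	
school	school	
she	she	
so	so	
take	take	
that	that	
the	the	
then	then	
to	to	
umbrella	umbrella	
walk	walk	
wet	wet	
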