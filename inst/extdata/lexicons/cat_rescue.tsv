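# task_id: CatRescue
# provenance: synthetic reconstruction for testing and demonstration; the normative list lives in the published core-lexicon norming studies and should be supplied by the user for real analyses
label	accepted_lemmas	extended_forms
a	a	
and	and	
be	be	
branch	branch	
call	call	
cat	cat	kittycat
climb	climb	
come	come	
dog	dog	
down	down	
father	father;dad;daddy;pa;papa	
fire	fire	
fireman	fireman	
get	get	
girl	girl	
go	go	
have	have	
he	he	
in	in	
it	it	
ladder	ladder	
little	little	
look	look	
not	not	
of	of	
out	out	
she	she	
so	so	
stuck	stuck;stick	
the	the	
to	to	
tree	tree	
truck	truck	
up	up	
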