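# task_id: Sandwich
# provenance: synthetic reconstruction for testing and demonstration; the normative list lives in the published core-lexicon norming studies and should be supplied by the user for real analyses
label	accepted_lemmas	extended_forms
a	a	
and	and	
bread	bread	
butter	butter	
get	get	
it	it	
jar	jar	
jelly	jelly	
knife	knife	
of	of	
on	on	
one	one	
open	open	
other	other	
peanut	peanut	
piece	piece	
put	put	
slice	slice	
spread	spread	
take	take	
the	the	
then	then	
to	to	
together	together	
top	top	
two	two	
with	with	
you	you	
lid	lid	
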