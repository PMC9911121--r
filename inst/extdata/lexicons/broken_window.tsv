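# task_id: BrokenWindow
# provenance: synthetic reconstruction for testing and demonstration; the normative list lives in the published core-lexicon norming studies and should be supplied by the user for real analyses
label	accepted_lemmas	extended_forms
a	a	
and	and	
ball	ball	
be	be	
boy	boy	
break	break	
go	go	
he	he	
his	his	
in	in	
it	it	
kick	kick	
lamp	lamp	
look	look	
of	of	
out	out	
over	over	
play	play	
sit	sit	
the	the	
through	through	
to	to	
up	up	
window	window	
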