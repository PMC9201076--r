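# Contextual modifier triggers (ConText-style).
# Columns: surface <TAB> type <TAB> direction
# type in {negation,historical,hypothetical,experiencer_other,pseudo,termination};
# pseudo triggers consume their span but open no scope; termination triggers
# close any open scope.
no	negation	forward
no evidence of	negation	forward
no new evidence of	negation	forward
without	negation	forward
without evidence of	negation	forward
denies	negation	forward
negative for	negation	forward
free of	negation	forward
absence of	negation	forward
not	negation	forward
never had	negation	forward
rules out	negation	forward
fails to reveal	negation	forward
was ruled out	negation	backward
is ruled out	negation	backward
not identified	negation	backward
not seen	negation	backward
unlikely	negation	backward
history of	historical	forward
known history of	historical	forward
prior history of	historical	forward
past medical history of	historical	forward
previous	historical	forward
previously	historical	forward
prior	historical	forward
status post	historical	forward
remote	historical	forward
if	hypothetical	forward
should	hypothetical	forward
could	hypothetical	forward
possible	hypothetical	forward
possibility of	hypothetical	forward
risk of	hypothetical	forward
concern for	hypothetical	forward
return if	hypothetical	forward
watch for	hypothetical	forward
monitor for	hypothetical	forward
rule out	hypothetical	forward
suspicious for	hypothetical	forward
family history of	experiencer_other	forward
father with	experiencer_other	forward
brother with	experiencer_other	forward
mother with	experiencer_other	forward
family member with	experiencer_other	forward
no increase	pseudo	forward
no change	pseudo	forward
no further	pseudo	forward
not only	pseudo	forward
gram negative	pseudo	forward
history of present illness	pseudo	forward
but	termination	forward
however	termination	forward
although	termination	forward
except	termination	forward
apart from	termination	forward
aside from	termination	forward
nevertheless	termination	forward
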