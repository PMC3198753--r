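# Null-pattern bank: normalized forms of whole responses that convey no
# health information. One pattern per line; lines are normalized on load
# (lower case, punctuation and digits stripped, whitespace collapsed).
# Matching removes the entire response, never individual words.
no
na
n a
none
nothing
nope
nah
negative no concerns
no comment
no comments
no concern
no concerns
no health concerns
no other concerns
no additional concerns
no additional comments
no further comments
no further concerns
no issues
no problems
no problem
no thanks
no thank you
no input
no response
no nothing
not really
not applicable
not at this time
none at this time
nothing at this time
nothing to add
nothing to report
nothing to say
i have nothing to say
i have no concerns
i have nothing to add
nothing comes to mind
none that i can think of
nothing i can think of
nothing else
nothing further
nothing more
nothing new
no more concerns
does not apply
all good
im good
i am good
im fine
i am fine
everything is fine
all is well
doing fine
fine
good
ok
okay
healthy
see above
same as above
covered above
already covered
blank
x
xx
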