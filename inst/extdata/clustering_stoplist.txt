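# High-frequency function-word stop list used ONLY when selecting clustering
# terms. Never applied during semantic-space construction: every word of every
# response enters the term-document matrix.
a
about
above
after
again
against
all
also
am
an
and
any
are
arent
as
at
be
because
been
before
being
below
between
both
but
by
can
cant
cannot
could
couldnt
did
didnt
do
does
doesnt
doing
done
dont
down
during
each
else
few
for
from
further
get
got
had
hadnt
has
hasnt
have
havent
having
he
her
here
hers
herself
him
himself
his
how
i
if
im
in
into
is
isnt
it
its
itself
ive
just
lot
many
may
me
might
more
most
much
must
my
myself
no
nor
not
now
of
off
on
once
only
or
other
our
ours
ourselves
out
over
own
per
same
she
should
shouldnt
since
so
some
such
than
that
the
their
theirs
them
themselves
then
there
these
they
this
those
through
to
too
under
until
up
upon
very
was
wasnt
we
were
werent
what
when
where
which
while
who
whom
why
will
with
within
without
wont
would
wouldnt
you
your
yours
yourself
yourselves
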