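# closed-class words: no inflected forms are generated for these
a
an
the
and
but
or
so
because
if
when
then
than
there
here
that
this
these
those
he
she
it
they
i
you
we
her
him
his
hers
its
their
them
my
your
me
us
of
in
on
at
by
for
with
to
into
onto
out
off
up
down
over
under
through
after
before
not
no
yes
all
one
two
three
other
together
back
very
who
what
which
too
again
away
about
little
some
any
every
each
how
why
where
now
just
while
kind
sort
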