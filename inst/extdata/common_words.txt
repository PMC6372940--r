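a
about
after
again
all
also
always
an
and
any
are
as
ask
at
away
back
bad
be
because
bed
been
before
best
better
big
body
book
boy
but
by
call
came
can
care
cat
child
clean
cold
come
could
day
did
do
doctor
does
dog
done
down
drink
each
eat
end
even
every
eye
face
family
far
fast
feel
feet
fell
few
find
fine
first
food
foot
for
found
friend
from
full
fun
get
girl
give
go
good
got
great
had
hand
happy
hard
has
have
he
head
hear
heart
help
her
here
him
his
home
hope
hot
house
how
hurt
i
if
in
into
is
it
its
just
keep
kind
know
last
left
leg
let
life
like
little
live
long
look
love
made
make
man
many
may
me
milk
mind
more
most
mother
much
must
my
name
near
need
never
new
next
nice
night
no
not
now
of
off
old
on
once
one
only
open
or
other
our
out
over
own
pain
part
people
place
play
put
rest
right
room
run
said
same
saw
say
school
see
she
show
sick
side
sit
sleep
small
so
some
soon
start
stay
still
stop
such
take
talk
tell
than
that
the
their
them
then
there
they
thing
think
this
time
tired
to
today
told
too
took
try
turn
two
under
up
us
use
very
walk
want
warm
was
water
way
we
week
well
went
were
what
when
where
which
while
who
why
will
with
work
would
year
yes
you
your
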