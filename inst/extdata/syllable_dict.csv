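word,syllables
a,1
about,2
after,2
again,2
almost,2
also,2
always,2
an,1
and,1
another,3
answer,2
any,2
are,1
area,3
around,2
as,1
assessment,3
at,1
attention,3
awareness,3
away,2
bad,1
be,1
because,2
bed,1
been,1
before,2
best,1
better,2
big,1
body,2
both,1
but,1
by,1
calm,1
can,1
care,1
caregiver,3
cat,1
cause,1
causes,2
chart,1
city,2
clear,1
cold,1
common,2
completely,3
complicated,4
condition,3
confusion,3
could,1
daily,2
day,1
delirium,4
dementia,3
detection,3
develop,3
did,1
different,3
difficult,3
direction,3
disorder,3
disorientation,6
do,1
doctor,2
does,1
dog,1
door,1
dose,1
drug,1
during,2
each,1
early,2
eat,1
effect,2
emotion,3
end,1
environment,4
especially,4
even,2
ever,2
example,3
experience,4
fact,1
fair,1
fall,1
family,3
fast,1
fear,1
fever,2
few,1
find,1
first,1
fluctuates,3
focus,2
for,1
found,1
friend,1
from,1
general,3
get,1
getting,2
give,1
go,1
gobbledygook,4
good,1
got,1
great,1
had,1
hallucination,5
hand,1
happen,2
hardly,2
has,1
have,1
having,2
he,1
head,1
health,1
hear,1
heart,1
help,1
her,1
here,1
high,1
him,1
his,1
home,1
hospital,3
how,1
however,3
identify,4
if,1
illness,2
important,3
in,1
infection,3
information,4
injury,3
inside,2
intervention,4
into,2
is,1
issue,2
it,1
item,2
its,1
just,1
keep,1
know,1
large,1
last,1
later,2
less,1
life,1
light,1
like,1
little,2
long,1
look,1
loss,1
lost,1
loud,1
low,1
made,1
make,1
man,1
many,2
mat,1
may,1
me,1
mean,1
medical,3
medication,4
medicine,3
member,2
memory,3
men,1
mental,2
mind,1
moment,2
monitoring,4
more,1
morning,2
most,1
much,1
must,1
my,1
near,1
need,1
never,2
new,1
next,1
night,1
no,1
noise,1
nor,1
not,1
now,1
number,2
nurse,1
observation,4
of,1
off,1
often,2
old,1
on,1
once,1
one,1
only,2
open,2
opportunity,5
or,1
other,2
our,1
out,1
over,2
pain,1
part,1
patient,2
people,2
person,2
physician,3
plan,1
poor,1
population,4
possible,3
prevalence,3
prevention,3
probably,3
problem,2
process,2
protection,3
provider,3
question,2
quickly,2
read,1
reason,2
recognize,3
recovery,4
regular,3
remember,3
rest,1
restless,2
risk,1
room,1
safe,1
safety,2
said,1
same,1
sat,1
say,1
security,4
see,1
serious,3
seven,2
several,3
she,1
shift,1
short,1
should,1
sick,1
side,1
sign,1
signs,1
simple,2
situation,4
sleep,1
sleeping,2
slow,1
small,1
so,1
some,1
soon,1
sound,1
staff,1
stay,1
step,1
still,1
stress,1
strong,1
such,1
sudden,2
suddenly,3
symptom,2
symptoms,2
table,2
take,1
talk,1
task,1
team,1
tell,1
ten,1
test,1
than,1
that,1
the,1
their,1
them,1
then,1
there,1
these,1
they,1
think,1
thinking,2
this,1
those,1
three,1
through,1
time,1
to,1
together,3
told,1
too,1
took,1
treatment,2
trouble,2
two,1
under,2
understand,3
university,5
up,1
us,1
use,1
very,2
visitor,3
walk,1
wandering,3
ward,1
was,1
watch,1
water,2
we,1
week,1
weekly,2
well,1
were,1
what,1
when,1
where,1
which,1
who,1
why,1
will,1
window,2
with,1
without,2
word,1
work,1
worry,2
would,1
year,1
yes,1
yet,1
you,1
your,1
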