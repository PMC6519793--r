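the
of
in
for
with
during
after
before
between
among
several
various
distinct
overall
general
regional
tissue
cells
samples
groups
cohort
subjects
animals
mice
rats
human
plasma
serum
protein
pathway
receptor
signaling
expression
levels
activity
function
role
effects
responses
changes
profiles
patterns
mechanisms
processes
conditions
parameters
values
data
results
findings
observations
differences
similar
consistent
robust
moderate
substantial
relative
mean
median
approximately
further
additional
together
respectively
however
moreover
furthermore
therefore
thus
also
present
important
major
minor
novel
common
rare
specific
broad
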