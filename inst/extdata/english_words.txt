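and
anterior
apex
arm
back
base
cone
cord
down
eye
eyes
field
final
initial
lateral
low
lower
medial
mid
modulate
neck
node
nodes
of
photon
photons
posterior
primary
proton
protons
retreat
setup
skin
spine
the
to
total
treat
up
upper
with
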