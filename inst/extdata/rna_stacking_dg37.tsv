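# Nearest-neighbor RNA/RNA duplex parameters, delta-G at 37 C (kcal/mol).
# Stack keys read 5'XY3'/3'ZW5' in alignment order (Z sits under X, W
# under Y): X pairs Z and Y pairs W; values for the
# 16 Watson-Crick/Watson-Crick stacks follow the Turner 2004 free-energy
# set. Stacks containing a G:U wobble pair use the single generic `wobble`
# entry. `initiation` is the duplex initiation penalty; interior unpaired
# stretches of L nucleotides between helices cost loop_base + loop_per_nt*L.
key	dg
AA/UU	-0.93
AU/UA	-1.10
AC/UG	-2.24
AG/UC	-2.08
UA/AU	-1.33
UU/AA	-0.93
UG/AC	-2.11
UC/AG	-2.35
CA/GU	-2.11
CU/GA	-2.08
CC/GG	-3.26
CG/GC	-2.36
GA/CU	-2.35
GU/CA	-2.24
GG/CC	-3.26
GC/CG	-3.42
wobble	-1.00
initiation	0.50
loop_base	0.50
loop_per_nt	0.30
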