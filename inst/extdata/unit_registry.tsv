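# Unit conversion registry: value_to = value_from * factor + offset.
# A self-row (factor 1, offset 0) registers a unit that has no default
# conversion partner; units are convertible only within the connected
# component ("dimension group") they share. Molar and mass-based
# concentration units are deliberately NOT connected by default: bridging
# micromolar to micromole-per-kilogram needs an explicit seawater-density
# assumption (see with_density_bridge()).
from_curie	to_curie	factor	offset
UO:0000062	UO:0000063	1000	0
UO:0000063	UO:0000064	1000	0
UO:0000064	UO:0000065	1000	0
UO:0000027	UO:0000012	1	273.15
UO:0010004	UO:0010004	1	0
UO:0000008	UO:0000008	1	0
UO:0000185	UO:0000185	1	0
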