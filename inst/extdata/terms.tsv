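# Ontology term table: flat is-a fragment of ENVO/UO/OBI/CHEBI/PATO/IAO/PMO
# covering marine sample metadata. parents = pipe-separated CURIEs.
# Hierarchy placement is simplified for fixture purposes (concentration
# attributes sit under the PATO concentration quality; sea water directly
# under liquid water). TEMP:-prefixed entries are synthetic provisional
# terms with no released ENVO identifier.
curie	label	parents
ENVO:00010483	environmental material
ENVO:00002006	liquid water	ENVO:00010483
ENVO:00002010	sea water	ENVO:00002006
PATO:0000033	concentration of
PATO:0001595	depth
ENVO:3100022	concentration of nitrate in liquid water	PATO:0000033
ENVO:3100036	concentration of chlorophyll in liquid water	PATO:0000033
ENVO:3100008	concentration of chlorophyll a in liquid water	ENVO:3100036
ENVO:3100011	concentration of dioxygen in liquid water	PATO:0000033
TEMP:0000001	concentration of phosphate in liquid water	PATO:0000033
TEMP:0000002	concentration of silicic acid in liquid water	PATO:0000033
ENVO:09200014	temperature of water
ENVO:00002297	environmental feature
ENVO:01000326	deep chlorophyll maximum layer	ENVO:00002297
ENVO:00000213	marine mesopelagic zone	ENVO:00002297
ENVO:01001581	sea surface layer	ENVO:00002297
ENVO:00000021	freshwater lake	ENVO:00002297
ENVO:00000032	bay	ENVO:00002297
ENVO:00000428	biome
ENVO:01000252	freshwater lake biome	ENVO:00000428
ENVO:01000253	freshwater river biome	ENVO:00000428
ENVO:01000020	estuarine biome	ENVO:00000428
ENVO:00000447	marine biome	ENVO:00000428
ENVO:01000204	tropical
ENVO:01000206	temperate
ENVO:01000238	polar
CHEBI:24431	chemical entity
CHEBI:28966	chlorophyll	CHEBI:24431
CHEBI:18230	chlorophyll a	CHEBI:28966
CHEBI:17632	nitrate	CHEBI:24431
CHEBI:18367	phosphate	CHEBI:24431
CHEBI:15379	dioxygen	CHEBI:24431
CHEBI:16526	carbon dioxide	CHEBI:24431
CHEBI:17996	chloride	CHEBI:24431
CHEBI:15377	water	CHEBI:24431
CHEBI:16301	nitrite	CHEBI:24431
CHEBI:28938	ammonium	CHEBI:24431
CHEBI:17234	glucose	CHEBI:24431
UO:0000000	unit
UO:0000062	molar	UO:0000000
UO:0000063	millimolar	UO:0000000
UO:0000064	micromolar	UO:0000000
UO:0000065	nanomolar	UO:0000000
UO:0010004	micromole per kilogram	UO:0000000
UO:0000027	degree Celsius	UO:0000000
UO:0000012	kelvin	UO:0000000
UO:0000185	degree	UO:0000000
UO:0000008	meter	UO:0000000
OBI:0000968	device
OBI:0001057	high performance liquid chromatography instrument	OBI:0000968
OBI:0400044	flow cytometer	OBI:0000968
OBI:0400143	fluorometer	OBI:0000968
OBI:0400169	microscope	OBI:0000968
OBI:0400115	spectrophotometer	OBI:0000968
OBI:0001620	latitude coordinate measurement datum
OBI:0001621	longitude coordinate measurement datum
OBI:0001619	specimen collection time measurement datum
IAO:0020000	identifier
PMO:00000076	latitude coordinate measurement datum start	OBI:0001620
PMO:00000079	latitude coordinate measurement datum stop	OBI:0001620
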