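donor	cell_type	obs_id
D01	CT1	C00001
D01	CT1	C00002
D01	CT1	C00003
D01	CT1	C00004
D01	CT1	C00005
D01	CT1	C00006
D01	CT1	C00007
D01	CT1	C00008
D01	CT1	C00009
D01	CT1	C00010
D02	CT1	C00011
D02	CT1	C00012
D02	CT1	C00013
D02	CT1	C00014
D02	CT1	C00015
D02	CT1	C00016
D02	CT1	C00017
D02	CT1	C00018
D02	CT1	C00019
D02	CT1	C00020
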