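name	targets	composition	delta_mass	role
la	K	C3H4O2	72.02113	target
cr	K	C4H4O	68.02621	target
hib	K	C4H6O2	86.03678	target
bz	K	C7H4O	104.02621	target
ac	K	C2H2O	42.01057	background
me1	K	CH2	14.01565	background
me2	K	C2H4	28.03130	background
me3	K	C3H6	42.04695	background
rme1	R	CH2	14.01565	background
rme2	R	C2H4	28.03130	background
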