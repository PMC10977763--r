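COX1	+
COX2	+
trnD	+
ATP8	+
ATP6	+
trnF	-
NAD5	-
trnH	-
NAD4	-
NAD4L	-
trnT	-
trnS2	-
CYTB	-
NAD6	-
trnP	-
NAD1	-
trnL2	-
trnL1	-
rrnL	-
trnV	-
rrnS	-
trnM	-
trnY	-
trnC	-
trnW	-
trnQ	-
trnG	-
trnE	-
COX3	+
trnK	+
trnA	+
trnR	+
trnN	+
trnI	+
NAD3	+
trnS1	+
NAD2	+
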