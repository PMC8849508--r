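# Worked graph-resolution example: a 12-node contig graph with one bubble
# (branches B1-B3 vs B2 between C2 and C3) and one repeat contig R flanked
# by C5/C6 on one side and C7/C8 on the other, with direct flank-to-flank
# edges C5-C8 and C6-C7 from joining sequences spanning the whole repeat.
# Expected resolution: three paths C1-C2-B1-B3-C3-C4, C5-R-C8, C6-R-C7,
# with R duplicated and B2 reported as a removed haplotype variant.
#node C1 10000
#node C2 8000
#node C3 9000
#node C4 7000
#node C5 12000
#node C6 11000
#node C7 9000
#node C8 10000
#node B1 4000
#node B2 4000
#node B3 3000
#node R 8000
C1	end	C2	begin	3	400
C2	end	B1	begin	3	350
C2	end	B2	begin	2	300
B1	end	B3	begin	3	250
B3	end	C3	begin	3	420
B2	end	C3	begin	2	380
C3	end	C4	begin	3	500
C5	end	R	begin	3	300
C6	end	R	begin	3	340
R	end	C7	begin	3	310
R	end	C8	begin	3	290
C5	end	C8	begin	2	8600
C6	end	C7	begin	2	8650
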