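##fileformat=VCFv4.2
##source=syntenic-caller (synthetic example in the caller's dialect)
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
Chr01	10183	SNP1	A	G	.	PASS	ChrB=Chr01;Parent=SYN1
Chr01	20450	SNP2	C	T	.	PASS	ChrB=Chr01;Parent=SYN1
Chr01	20450	SNP2b	C	T	.	PASS	ChrB=Chr01;Parent=SYN2;DupType=copy
Chr01	31077	DEL1	GAACCTTAG	G	.	PASS	ChrB=Chr01;Parent=SYN2
Chr02	5512	INS1.1	T	TACGTACCG	.	PASS	ChrB=Chr02;Parent=SYN3;DupType=fragment
Chr02	5512	INS1.2	T	TGGATTA	.	PASS	ChrB=Chr02;Parent=SYN3;DupType=fragment
Chr02	44230	DEL2	ATTTTCTCTTGGAAAACCCCTTTGGGGAAAACCCCTTTTGGGGAAAACCCCTTTAG	A	.	PASS	ChrB=Chr02;Parent=SYN4
Chr02	51209	INV1	G	<INV>	.	PASS	ChrB=Chr02;Parent=SYN5;END=63110
Chr03	7801	SNP3	G	A	.	PASS	ChrB=Chr03;Parent=SYN6
Chr03	7801	SNP3b	G	A	.	PASS	ChrB=Chr03;Parent=SYN6;DupType=copy
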