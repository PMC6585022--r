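# Schematic topologies of the 16 gene families entering the co-duplication
# comparison, one rooted mini-newick per family with human-chromosome leaf
# labels, together with the published per-panel translocation assumption
# (`allowance` = number of independent translocation events posited for that
# comparison set; panels are the published figure panels a-d).
family	panel	allowance	schematic
MROH	a	3	((20,1),8);
STK	a	3	((2,13),X);
E2F	b	2	((6,8),20);
EYA	b	2	((1,6),20);
STMN	b	2	((1,8),20);
HCK	c	5	((20,8),(1,8));
DLGAP	c	5	((20,18),(1,8));
NKAIN	c	5	((20,8),(1,6));
KCNQ	c	5	((20,8),(1,6));
MATN	c	5	((20,8),(1,2));
FAM110	d	4	((20,8),2);
NCOA	d	4	((20,8),2);
KCNS	d	4	((20,8),2);
YTHDF	d	4	((20,8),1);
XKR	d	4	((20,8),1);
MYT	d	4	((20,8),2);
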