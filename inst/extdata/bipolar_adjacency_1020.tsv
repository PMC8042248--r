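name	anode	cathode	homologue
Fp1-Fp2	Fp1	Fp2	Fp1-Fp2
F7-F3	F7	F3	F8-F4
F3-Fz	F3	Fz	Fz-F4
Fz-F4	Fz	F4	F3-Fz
F8-F4	F8	F4	F7-F3
T3-C3	T3	C3	T4-C4
C3-Cz	C3	Cz	Cz-C4
Cz-C4	Cz	C4	C3-Cz
T4-C4	T4	C4	T3-C3
T5-P3	T5	P3	T6-P4
P3-Pz	P3	Pz	Pz-P4
Pz-P4	Pz	P4	P3-Pz
T6-P4	T6	P4	T5-P3
O1-O2	O1	O2	O1-O2
Fp1-F7	Fp1	F7	Fp2-F8
Fp1-F3	Fp1	F3	Fp2-F4
Fp2-F4	Fp2	F4	Fp1-F3
Fp2-F8	Fp2	F8	Fp1-F7
F7-T3	F7	T3	F8-T4
T3-T5	T3	T5	T4-T6
F3-C3	F3	C3	F4-C4
C3-P3	C3	P3	C4-P4
Fz-Cz	Fz	Cz	Fz-Cz
Cz-Pz	Cz	Pz	Cz-Pz
F4-C4	F4	C4	F3-C3
C4-P4	C4	P4	C3-P3
F8-T4	F8	T4	F7-T3
T4-T6	T4	T6	T3-T5
T5-O1	T5	O1	T6-O2
P3-O1	P3	O1	P4-O2
P4-O2	P4	O2	P3-O1
T6-O2	T6	O2	T5-O1
Fp1-Fz	Fp1	Fz	Fp2-Fz
Fp2-Fz	Fp2	Fz	Fp1-Fz
Pz-O1	Pz	O1	Pz-O2
Pz-O2	Pz	O2	Pz-O1
F7-C3	F7	C3	F8-C4
T3-F3	T3	F3	T4-F4
F3-Cz	F3	Cz	F4-Cz
Fz-C3	Fz	C3	Fz-C4
Fz-C4	Fz	C4	Fz-C3
F4-Cz	F4	Cz	F3-Cz
F8-C4	F8	C4	F7-C3
T4-F4	T4	F4	T3-F3
T3-P3	T3	P3	T4-P4
T5-C3	T5	C3	T6-C4
C3-Pz	C3	Pz	C4-Pz
Cz-P3	Cz	P3	P4-Cz
P4-Cz	P4	Cz	Cz-P3
C4-Pz	C4	Pz	C3-Pz
T4-P4	T4	P4	T3-P3
T6-C4	T6	C4	T5-C3
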