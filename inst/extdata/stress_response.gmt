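HEAT_SHOCK_RESPONSE	HSF1-driven chaperone induction	HSPA6	HSPA1A	HSPA1B	HSPB1	DNAJB1	DNAJA1	HSPH1	HSPD1	HSPE1	BAG3
INTEGRATED_STRESS_DNA_DAMAGE	ER/DNA-damage stress transcripts	DDIT3	ATF3	ATF4	GADD45A	GADD45B	PPP1R15A	JUN	FOS	EGR1	TRIB3
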