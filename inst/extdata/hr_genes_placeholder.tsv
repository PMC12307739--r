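gene	group
BRCA1	BRCA12
BRCA2	BRCA12
ATM	other_HR
ATR	other_HR
ATRX	other_HR
BAP1	other_HR
BARD1	other_HR
BLM	other_HR
BRIP1	other_HR
CDK12	other_HR
CHEK1	other_HR
CHEK2	other_HR
FANCA	other_HR
FANCC	other_HR
FANCD2	other_HR
FANCE	other_HR
FANCF	other_HR
FANCG	other_HR
FANCI	other_HR
FANCL	other_HR
FANCM	other_HR
MRE11	other_HR
NBN	other_HR
PALB2	other_HR
RAD50	other_HR
RAD51	other_HR
RAD51B	other_HR
RAD51C	other_HR
RAD51D	other_HR
RAD52	other_HR
RAD54B	other_HR
RAD54L	other_HR
RPA1	other_HR
WRN	other_HR
XRCC2	other_HR
XRCC3	other_HR
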