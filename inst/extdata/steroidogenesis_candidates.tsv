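gene	category
CYP17A1	Steroidogenesis
CYP11A1	Steroidogenesis
STAR	Steroidogenesis
FDX1P1	Steroidogenesis
FDX1	Steroidogenesis
PAPSS2	Steroidogenesis
HSD3B2	Steroidogenesis
POR	Steroidogenesis
SERPINA5	Cholesterol metabolism & oxidative stress
SCARB1	Cholesterol metabolism & oxidative stress
DHCR24	Cholesterol metabolism & oxidative stress
APOA1	Cholesterol metabolism & oxidative stress
APOC1	Cholesterol metabolism & oxidative stress
MSMO1	Cholesterol metabolism & oxidative stress
AS3MT	Cholesterol metabolism & oxidative stress
LDLR	Cholesterol metabolism & oxidative stress
DHCR7	Cholesterol metabolism & oxidative stress
ACSS1	Cholesterol metabolism & oxidative stress
NPC1	Cholesterol metabolism & oxidative stress
PDK4	Cholesterol metabolism & oxidative stress
ABCA5	Cholesterol metabolism & oxidative stress
IDI1	Cholesterol metabolism & oxidative stress
GPD1L	Cholesterol metabolism & oxidative stress
HMGCR	Cholesterol metabolism & oxidative stress
GSTA1	Oxidative stress
MGST1	Oxidative stress
SLC8B1	Oxidative stress
GSTA3	Oxidative stress
MGARP	Novel
MAP3K15	Novel
HPGD	Novel
C7	Novel
MT2A	Novel
DLK1	Novel
INHA	Novel
FOXO4	Novel
GRAMD1B	Novel
RMDN2	Novel
SLC46A3	Novel
SLC16A9	Novel
COL15A1	Novel
AVPI1	Novel
FRRS1	Novel
VCAM1	Novel
FLJ38894	Novel
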